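new_sample_profile <- function(df, sample_id, kind) {
  stopifnot(kind %in% c("dna", "rna"))
  structure(df, sample_id = sample_id, kind = kind,
            class = c("sample_profile", "data.frame"))
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile '", attr(x, "sample_id"), "' (", attr(x, "kind"), "): ",
      nrow(x), " splits, mean coverage ",
      signif(mean(x$mean_coverage), 4), "\n", sep = "")
  invisible(x)
}

#' Profile a BAM file against a contigs table
#'
#' Computes, for every split, the mean per-base read depth and the
#' detection (breadth of coverage: fraction of positions covered by at
#' least one read). All primary alignments are counted irrespective of
#' pairing or mapping quality; secondary and supplementary records are
#' excluded by default. Deleted reference positions (CIGAR D) contribute
#' no depth; insertions are ignored.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file whose
#'   reference names match the assembly's scaffold names.
#' @param contigs A `contigs_table` built from the same assembly.
#' @param sample_id Library name for this profile.
#' @param kind `"dna"` or `"rna"`; RNA-seq is profiled identically, its
#'   detection values being the statistic used downstream.
#' @param include_secondary Count secondary/supplementary alignments too.
#' @return A `sample_profile`: data.frame with columns `split_name`,
#'   `mean_coverage`, `detection`, one row per split in contigs-table
#'   order, with attributes `sample_id` and `kind`.
#' @export
profile_alignment <- function(bam_path, contigs, sample_id,
                              kind = "dna", include_secondary = FALSE) {
  stopifnot(inherits(contigs, "contigs_table"))
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai))) {
    stop("BAM index not found for '", bam_path,
         "'; index it first (e.g. samtools index, or Rsamtools::indexBam)")
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  scaffolds <- unique(contigs$splits$parent)
  shared <- intersect(names(hdr), scaffolds)
  if (length(shared) == 0) {
    stop("BAM '", bam_path, "' shares no reference names with the assembly; ",
         "reads were mapped to a different reference")
  }
  missing <- setdiff(scaffolds, names(hdr))
  if (length(missing) > 0) {
    warning(length(missing), " scaffolds absent from BAM references ",
            "(reported as zero coverage), e.g. ", missing[1])
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (include_secondary) NA else FALSE
  )
  aln <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(flag = flag))
  cov <- GenomicAlignments::coverage(aln, drop.D.ranges = TRUE)

  sp <- contigs$splits
  mean_cov <- numeric(nrow(sp))
  det <- numeric(nrow(sp))
  for (sc in unique(sp$parent)) {
    idx <- which(sp$parent == sc)
    if (!sc %in% names(cov)) next
    depth <- cov[[sc]]
    v <- IRanges::Views(depth, start = sp$start[idx] + 1L, end = sp$end[idx])
    mean_cov[idx] <- IRanges::viewSums(v) / sp$length[idx]
    nz <- S4Vectors::Rle(as.integer(S4Vectors::runValue(depth) > 0),
                         S4Vectors::runLength(depth))
    vz <- IRanges::Views(nz, start = sp$start[idx] + 1L, end = sp$end[idx])
    det[idx] <- IRanges::viewSums(vz) / sp$length[idx]
  }
  new_sample_profile(
    data.frame(split_name = sp$split_name, mean_coverage = mean_cov,
               detection = det, stringsAsFactors = FALSE),
    sample_id = sample_id, kind = kind
  )
}

#' Load a per-split coverage profile from a TSV
#'
#' BAM-free entry point: reads a table with columns `split_name`,
#' `mean_coverage`, `detection` and validates it against the contigs
#' table (every split present exactly once, coverage >= 0, detection in
#' `[0, 1]`, zero detection implies zero coverage).
#'
#' @param tsv_path Path to the profile TSV (with header).
#' @inheritParams profile_alignment
#' @return A `sample_profile` in contigs-table row order.
#' @export
profile_table <- function(tsv_path, contigs, sample_id, kind = "dna") {
  stopifnot(inherits(contigs, "contigs_table"))
  df <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("split_name", "mean_coverage", "detection")
  if (!all(need %in% names(df))) {
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$split_name)) stop("duplicate split names in profile TSV")
  missing <- setdiff(contigs$splits$split_name, df$split_name)
  if (length(missing) > 0) {
    stop("profile TSV is missing ", length(missing), " splits: ",
         paste(head(missing, 5), collapse = ", "))
  }
  unknown <- setdiff(df$split_name, contigs$splits$split_name)
  if (length(unknown) > 0) {
    stop("profile TSV has unknown split names: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  df <- df[match(contigs$splits$split_name, df$split_name), need]
  rownames(df) <- NULL
  if (any(df$mean_coverage < 0)) stop("negative mean_coverage in profile TSV")
  if (any(df$detection < 0 | df$detection > 1)) {
    stop("detection outside [0, 1] in profile TSV")
  }
  if (any(df$detection == 0 & df$mean_coverage > 0)) {
    stop("profile TSV violates: detection == 0 implies mean_coverage == 0")
  }
  new_sample_profile(df, sample_id = sample_id, kind = kind)
}

#' Merge per-library profiles into coverage matrices
#'
#' @param profiles List of `sample_profile` objects over the same contigs.
#' @param contigs The shared `contigs_table`.
#' @return A `coverage_set`: list with `samples` (data.frame `sample_id`,
#'   `kind`, in input order), `mean` and `detection` (splits x samples
#'   matrices, rows in contigs-table order).
#' @export
merge_profiles <- function(profiles, contigs) {
  stopifnot(length(profiles) >= 1, inherits(contigs, "contigs_table"))
  ids <- vapply(profiles, attr, character(1), which = "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among profiles: ",
                               ids[duplicated(ids)][1])
  kinds <- vapply(profiles, attr, character(1), which = "kind")
  sn <- contigs$splits$split_name
  mk <- function(col) {
    m <- vapply(profiles, function(p) {
      if (!identical(p$split_name, sn)) {
        if (!setequal(p$split_name, sn)) {
          stop("profile '", attr(p, "sample_id"),
               "' does not cover the same splits as the contigs table")
        }
        p <- p[match(sn, p$split_name), ]
      }
      p[[col]]
    }, numeric(length(sn)))
    m <- matrix(m, nrow = length(sn), dimnames = list(sn, ids))
    m
  }
  structure(list(samples = data.frame(sample_id = ids, kind = kinds,
                                      stringsAsFactors = FALSE),
                 mean = mk("mean_coverage"),
                 detection = mk("detection")),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("coverage_set:", nrow(x$mean), "splits x", ncol(x$mean), "samples (",
      sum(x$samples$kind == "dna"), "dna,", sum(x$samples$kind == "rna"),
      "rna )\n")
  invisible(x)
}

#' Write a sample profile, or a merged coverage set, to TSV
#'
#' @param x A `sample_profile` or `coverage_set`.
#' @param path For a profile, the output TSV; for a coverage set, a
#'   directory receiving `mean_coverage.tsv` and `detection.tsv` (wide,
#'   rows = splits, columns = samples).
#' @return `path`, invisibly.
#' @export
write_coverage <- function(x, path) {
  if (inherits(x, "sample_profile")) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "coverage_set")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("mean", "detection")) {
      df <- data.frame(split_name = rownames(x[[nm]]), x[[nm]],
                       check.names = FALSE)
      out <- file.path(path, c(mean = "mean_coverage.tsv",
                               detection = "detection.tsv")[[nm]])
      write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else stop("unsupported object")
  invisible(path)
}
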