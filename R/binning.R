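#' Load a bin selection over splits
#'
#' A selection maps split names to bin labels; splits may be left
#' unassigned. The file stands in for interactive selection on the
#' clustering: typically produced by [cut_tree()] or by hand.
#'
#' @param tsv_path TSV with columns `split_name`, `bin` (header optional).
#'   An empty file is an empty selection.
#' @param contigs The `contigs_table` the split names must belong to.
#' @return A `bin_selection`: named character vector, split name -> bin
#'   label.
#' @export
load_selection <- function(tsv_path, contigs) {
  stopifnot(inherits(contigs, "contigs_table"))
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^split_name\t", lines[1])) lines <- lines[-1]
  if (length(lines) == 0) {
    return(as_bin_selection(setNames(character(0), character(0)), contigs))
  }
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2)) {
    stop("selection TSV must have exactly 2 tab-separated columns ",
         "(split_name, bin); offending line ",
         which(lengths(parts) != 2)[1])
  }
  m <- do.call(rbind, parts)
  as_bin_selection(setNames(m[, 2], m[, 1]), contigs)
}

#' Construct a bin selection from a named vector
#'
#' @param x Named character vector (or coercible), split name -> bin label.
#' @param contigs The `contigs_table` to validate against.
#' @return A `bin_selection`.
#' @export
as_bin_selection <- function(x, contigs) {
  x <- setNames(as.character(x), names(x))
  if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("selection must be named by split_name")
  }
  if (any(!nzchar(x))) stop("bin labels must be non-empty strings")
  unknown <- setdiff(names(x), contigs$splits$split_name)
  if (length(unknown) > 0) {
    stop("selection refers to unknown split names: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(names(x))) {
    d <- names(x)[duplicated(names(x))]
    conflict <- vapply(unique(d),
                       function(s) length(unique(x[names(x) == s])) > 1,
                       logical(1))
    if (any(conflict)) {
      stop("split(s) assigned to conflicting bins: ",
           paste(head(unique(d)[conflict], 5), collapse = ", "))
    }
    x <- x[!duplicated(names(x))]
  }
  structure(x, class = "bin_selection")
}

#' Resolve split-level selections to scaffold-level bins
#'
#' Selections are made over splits, but curation is reported and exported
#' over whole scaffolds. A scaffold is assigned to the bin holding the
#' majority of its assigned split length; ties leave it unassigned (with
#' a warning), as do scaffolds with no assigned splits.
#'
#' @param selection A `bin_selection`.
#' @param contigs The `contigs_table`.
#' @return Named character vector, scaffold name -> bin label, covering
#'   only assigned scaffolds.
#' @export
resolve_scaffolds <- function(selection, contigs) {
  sp <- contigs$splits
  idx <- match(names(selection), sp$split_name)
  if (length(idx) == 0) return(setNames(character(0), character(0)))
  df <- data.frame(parent = sp$parent[idx], bin = as.character(selection),
                   len = sp$length[idx], stringsAsFactors = FALSE)
  agg <- stats::aggregate(len ~ parent + bin, data = df, FUN = sum)
  out <- character(0)
  ties <- character(0)
  for (sc in unique(agg$parent)) {
    a <- agg[agg$parent == sc, ]
    top <- a$bin[a$len == max(a$len)]
    if (length(top) == 1) out[sc] <- top else ties <- c(ties, sc)
  }
  if (length(ties) > 0) {
    warning(length(ties), " scaffold(s) left unassigned due to tied ",
            "split-length majority: ", paste(head(ties, 5), collapse = ", "))
  }
  out
}

rna_mass <- function(coverage, rna_samples, contigs) {
  det <- coverage$detection[, rna_samples, drop = FALSE]
  rowSums(det) * contigs$splits$length[match(rownames(det),
                                             contigs$splits$split_name)]
}

#' Per-bin curation report
#'
#' For every bin (plus the unassigned remainder) reports scaffold and
#' split counts, total length, length-weighted mean GC, per-sample
#' length-weighted mean coverage and detection, the single-copy-gene
#' census (completeness, redundancy, estimated genomes), the fraction of
#' total RNA signal recruited by the bin, and the overlap with an
#' optional external annotation list (e.g. scaffolds flagged as carrying
#' proposed HGTs).
#'
#' RNA recruitment of bin B is the detection-length mass of B's splits in
#' the RNA samples over the total mass across all splits (0/0 is 0) — a
#' proxy for the fraction of transcriptome reads mapping to the bin.
#' Recruitment sums to 1 over bins plus unassigned whenever any RNA
#' signal exists.
#'
#' @param selection A `bin_selection`.
#' @param contigs The `contigs_table`.
#' @param coverage A `coverage_set` over the same splits.
#' @param hits An `scg_hits` table.
#' @param collection The `scg_collection`.
#' @param annotations Optional character vector of flagged scaffold names
#'   (see [load_annotation()]); names absent from the assembly are
#'   reported via a warning and ignored.
#' @param rna_samples Character vector of RNA sample ids in `coverage`
#'   (empty -> RNA columns reported as NA).
#' @return A `bin_report` data.frame, one row per bin plus `"unassigned"`.
#' @export
bin_report <- function(selection, contigs, coverage, hits, collection,
                       annotations = NULL, rna_samples = character(0)) {
  stopifnot(inherits(contigs, "contigs_table"),
            inherits(coverage, "coverage_set"))
  if (length(rna_samples) > 0) {
    missing <- setdiff(rna_samples, coverage$samples$sample_id)
    if (length(missing) > 0) {
      stop("RNA sample(s) absent from coverage set: ",
           paste(missing, collapse = ", "))
    }
  }
  sc2bin <- resolve_scaffolds(selection, contigs)
  sp <- contigs$splits
  scaffolds <- unique(sp$parent)
  bin_of_scaffold <- setNames(rep("unassigned", length(scaffolds)), scaffolds)
  bin_of_scaffold[names(sc2bin)] <- sc2bin
  bins <- c(setdiff(unique(sc2bin), "unassigned"), "unassigned")

  ann_in <- character(0)
  if (!is.null(annotations)) {
    unmatched <- setdiff(annotations, scaffolds)
    if (length(unmatched) > 0) {
      warning(length(unmatched), " annotated scaffold name(s) not in the ",
              "assembly: ", paste(head(unmatched, 5), collapse = ", "))
    }
    ann_in <- intersect(annotations, scaffolds)
  }
  mass <- if (length(rna_samples) > 0) rna_mass(coverage, rna_samples, contigs)
          else NULL
  total_mass <- if (is.null(mass)) NA_real_ else sum(mass)

  rows <- lapply(bins, function(b) {
    members <- scaffolds[bin_of_scaffold[scaffolds] == b]
    msplits <- splits_of(contigs, members)
    i <- match(msplits, sp$split_name)
    len <- sp$length[i]
    tot <- sum(len)
    cr <- bin_completeness_redundancy(hits, collection, msplits)
    cs <- census(hits, collection, subset = msplits)
    wmean <- function(m) {
      if (tot == 0) return(setNames(rep(0, ncol(m)), colnames(m)))
      colSums(m[i, , drop = FALSE] * len) / tot
    }
    rec <- if (is.null(mass)) NA_real_
           else if (total_mass == 0) 0
           else sum(mass[i]) / total_mass
    ann_n <- sum(ann_in %in% members)
    row <- data.frame(
      bin = b, n_scaffolds = length(members), n_splits = length(msplits),
      total_length = tot,
      mean_gc = if (tot == 0) NA_real_ else sum(sp$gc[i] * len) / tot,
      completeness = unname(cr["completeness"]),
      redundancy = unname(cr["redundancy"]),
      estimated_genomes = cs$estimated_genomes,
      multimodal = cs$multimodal,
      rna_recruitment = rec,
      annotated_scaffolds = ann_n,
      annotated_fraction = if (length(ann_in) == 0) NA_real_
                           else ann_n / length(ann_in),
      stringsAsFactors = FALSE
    )
    mc <- wmean(coverage$mean)
    dt <- wmean(coverage$detection)
    names(mc) <- paste0("mean_coverage_", coverage$samples$sample_id)
    names(dt) <- paste0("detection_", coverage$samples$sample_id)
    cbind(row, as.data.frame(t(mc)), as.data.frame(t(dt)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bin_report", "data.frame")
  out
}

#' Load an external scaffold annotation list
#'
#' One scaffold name per line (`#` comments allowed); e.g. a published
#' list of scaffolds carrying proposed horizontal gene transfers, used as
#' an overlay when judging bins.
#'
#' @param path Path to the list file.
#' @return Character vector of scaffold names.
#' @export
load_annotation <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Flag scaffolds detected only in auxiliary libraries
#'
#' A scaffold detected (breadth of coverage >= `detection_min` over at
#' least one of its splits) only in auxiliary libraries — e.g. long-read
#' Moleculo/PacBio preparations — but in none of the core short-read
#' libraries is a strong contamination signal: genuine host scaffolds
#' recruit reads from every preparation of the same DNA.
#'
#' @param coverage A `coverage_set`.
#' @param contigs The matching `contigs_table`.
#' @param core_samples,aux_samples Disjoint, non-empty character vectors
#'   of sample ids (core = the libraries every true host scaffold is
#'   expected in).
#' @param detection_min Detection threshold for calling a scaffold
#'   present in a library (default 0.5: at least half the scaffold
#'   covered).
#' @return data.frame with columns `scaffold`, `flag` in
#'   `{"core_supported", "aux_only", "undetected"}`.
#' @export
flag_library_restricted <- function(coverage, contigs, core_samples,
                                    aux_samples, detection_min = 0.5) {
  stopifnot(length(core_samples) > 0, length(aux_samples) > 0)
  if (length(intersect(core_samples, aux_samples)) > 0) {
    stop("core and aux sample lists must be disjoint")
  }
  unknown <- setdiff(c(core_samples, aux_samples), coverage$samples$sample_id)
  if (length(unknown) > 0) {
    stop("unknown sample name(s): ", paste(unknown, collapse = ", "))
  }
  sp <- contigs$splits
  det <- coverage$detection[sp$split_name, , drop = FALSE]
  scaffolds <- unique(sp$parent)
  core_max <- tapply(apply(det[, core_samples, drop = FALSE], 1, max),
                     sp$parent, max)[scaffolds]
  aux_max <- tapply(apply(det[, aux_samples, drop = FALSE], 1, max),
                    sp$parent, max)[scaffolds]
  flag <- ifelse(core_max >= detection_min, "core_supported",
                 ifelse(aux_max >= detection_min, "aux_only", "undetected"))
  data.frame(scaffold = scaffolds, flag = unname(flag),
             stringsAsFactors = FALSE)
}

#' Export curated bins as FASTA
#'
#' Writes one FASTA per bin (plus `unassigned`) containing the full
#' original scaffold sequences — never split fragments — and an index TSV
#' (`scaffold`, `bin`, `length`). Empty bins produce no file.
#'
#' @param selection A `bin_selection`.
#' @param contigs The `contigs_table`.
#' @param assembly_fasta Path to the assembly FASTA containing every
#'   resolved scaffold.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the index data.frame.
#' @export
export_bins <- function(selection, contigs, assembly_fasta, out_dir) {
  asm <- Biostrings::readDNAStringSet(assembly_fasta)
  names(asm) <- sub("\\s.*$", "", names(asm))
  sc2bin <- resolve_scaffolds(selection, contigs)
  scaffolds <- unique(contigs$splits$parent)
  bin_of <- setNames(rep("unassigned", length(scaffolds)), scaffolds)
  bin_of[names(sc2bin)] <- sc2bin
  missing <- setdiff(scaffolds, names(asm))
  if (length(missing) > 0) {
    stop("scaffold(s) missing from '", assembly_fasta, "': ",
         paste(head(missing, 5), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (b in unique(bin_of)) {
    members <- scaffolds[bin_of == b]
    if (length(members) == 0) {
      message("bin '", b, "' is empty; no FASTA written")
      next
    }
    Biostrings::writeXStringSet(asm[members],
                                file.path(out_dir, paste0(b, ".fa")))
  }
  idx <- data.frame(scaffold = scaffolds, bin = unname(bin_of[scaffolds]),
                    length = Biostrings::width(asm[scaffolds]),
                    stringsAsFactors = FALSE)
  write.table(idx, file.path(out_dir, "bins_index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(idx)
}
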