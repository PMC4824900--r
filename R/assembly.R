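#' Read a genome assembly and apply the minimum-length filter
#'
#' Reads a (possibly gzipped) multi-FASTA of assembly scaffolds, uppercases
#' sequences, replaces IUPAC ambiguity codes other than N by N, and drops
#' scaffolds shorter than `min_length`. The threshold is inclusive: a
#' scaffold of exactly `min_length` bases is retained.
#'
#' @param fasta_path Path to a FASTA file of scaffolds.
#' @param min_length Minimum scaffold length in bases (default 1000, the
#'   conventional profiling cutoff below which composition and coverage
#'   statistics become too noisy to cluster).
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-token
#'   of each FASTA header, in file order.
#' @export
read_assembly <- function(fasta_path, min_length = 1000L) {
  stopifnot(length(fasta_path) == 1L, min_length >= 0)
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    dups <- unique(names(x)[duplicated(names(x))])
    stop("duplicate scaffold names in '", fasta_path, "': ",
         paste(head(dups, 5), collapse = ", "))
  }
  x <- Biostrings::replaceAmbiguities(x, new = "N")
  x[Biostrings::width(x) >= min_length]
}

#' Split coordinates for one scaffold
#'
#' Scaffolds strictly longer than `split_threshold` are cut into
#' `floor(length / split_target)` contiguous sections of near-equal size
#' (lengths differ by at most one base, and no section is shorter than
#' `split_target`); shorter scaffolds stay whole. Coordinates are 0-based,
#' half-open.
#'
#' @param length Scaffold length in bases.
#' @param split_target Target section size in bases (default 20000).
#' @param split_threshold Scaffolds longer than this are split
#'   (default 40000; the comparison is strict).
#' @return A data.frame with columns `start` and `end` (0-based, half-open)
#'   tiling `[0, length)`.
#' @export
split_coords <- function(length, split_target = 20000L, split_threshold = 40000L) {
  stopifnot(length >= 1, split_target > 0, split_threshold >= split_target)
  if (length <= split_threshold) {
    return(data.frame(start = 0, end = length))
  }
  n <- length %/% split_target
  # near-equal partition: the first (length mod n) pieces get one extra base
  base <- length %/% n
  extra <- length %% n
  sizes <- rep(base, n)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  data.frame(start = c(0, ends[-n]), end = ends)
}

#' GC-content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); characters outside A/C/G/T are
#' excluded from both numerator and denominator. Returns 0 when the
#' sequence contains no unambiguous base.
#'
#' @param sequence A character string or [Biostrings::DNAString].
#' @return A fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  f <- Biostrings::letterFrequency(sequence, letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(0)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Canonical k-mers
#'
#' All k-mers over {A,C,G,T}, each collapsed with its reverse complement to
#' the lexicographically smaller of the pair, deduplicated and sorted. For
#' k = 4 this yields the 136 canonical tetranucleotides.
#'
#' @param k Word size.
#' @return Sorted character vector of canonical k-mers.
#' @export
canonical_kmers <- function(k = 4L) {
  stopifnot(k >= 1)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  sort(unique(pmin(kmers, rc)))
}

#' Tetranucleotide (k-mer) frequency vector
#'
#' Slides a window of `k` over the sequence; windows containing any
#' character outside A/C/G/T are skipped. Each valid k-mer is collapsed
#' with its reverse complement to its canonical form (assembly scaffolds
#' have arbitrary strand) and counts are normalized to frequencies summing
#' to 1. With no valid window the vector is all zeros.
#'
#' @param sequence A character string or [Biostrings::DNAString].
#' @param k Word size (default 4).
#' @param collapse Collapse reverse complements to canonical k-mers
#'   (default TRUE, 136 features for k = 4); FALSE keeps all `4^k` words.
#' @return Named numeric vector of frequencies over sorted (canonical)
#'   k-mers.
#' @export
tnf_vector <- function(sequence, k = 4L, collapse = TRUE) {
  stopifnot(k >= 1)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  feats <- if (collapse) canonical_kmers(k)
           else Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
  out <- setNames(numeric(length(feats)), feats)
  if (length(sequence) < k) return(out)
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = k)
  if (collapse) {
    kmers <- names(counts)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rc)
    counts <- tapply(counts, canon, sum)
  }
  tot <- sum(counts)
  if (tot == 0) return(out)
  out[names(counts)] <- counts / tot
  out
}

#' Build the contigs table for an assembly
#'
#' Cuts every scaffold into splits (see [split_coords()]) and computes
#' per-split length, GC-content and the canonical k-mer frequency vector.
#' The split is the unit of profiling and clustering throughout the
#' package, so long scaffolds contribute multiple observations.
#'
#' @param assembly A named [Biostrings::DNAStringSet], e.g. from
#'   [read_assembly()] (the minimum-length filter is applied there).
#' @param split_target,split_threshold See [split_coords()].
#' @param k k-mer size for composition features (default 4).
#' @param collapse Collapse k-mers with reverse complements (default TRUE).
#' @return An object of class `contigs_table`: a list with
#'   \describe{
#'     \item{splits}{data.frame with columns `split_name`, `parent`,
#'       `start`, `end`, `length`, `gc` (splits of one scaffold tile it
#'       exactly; names are `<parent>_split_<zero-padded ordinal>`).}
#'     \item{tnf}{numeric matrix, one row per split (rownames =
#'       `split_name`), columns the sorted canonical k-mers.}
#'     \item{params}{list recording `min_length` (attribute of the input if
#'       present, else NA), `split_target`, `split_threshold`, `k`,
#'       `collapse`.}
#'   }
#' @export
make_contigs <- function(assembly, split_target = 20000L,
                         split_threshold = 40000L, k = 4L, collapse = TRUE) {
  stopifnot(methods::is(assembly, "DNAStringSet"))
  if (is.null(names(assembly)) || anyDuplicated(names(assembly))) {
    stop("assembly must have unique scaffold names")
  }
  feats <- if (collapse) canonical_kmers(k)
           else Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
  rows <- vector("list", length(assembly))
  tnfs <- vector("list", length(assembly))
  for (i in seq_along(assembly)) {
    sc <- assembly[[i]]
    nm <- names(assembly)[i]
    co <- split_coords(length(sc), split_target, split_threshold)
    pad <- max(5L, nchar(nrow(co)))
    split_names <- sprintf("%s_split_%0*d", nm, pad, seq_len(nrow(co)))
    segs <- Biostrings::DNAStringSet(sc, start = co$start + 1L, end = co$end)
    gc <- vapply(seq_along(segs), function(j) gc_content(segs[[j]]), numeric(1))
    rows[[i]] <- data.frame(
      split_name = split_names, parent = nm,
      start = co$start, end = co$end, length = co$end - co$start, gc = gc,
      stringsAsFactors = FALSE
    )
    tnfs[[i]] <- t(vapply(seq_along(segs),
                          function(j) tnf_vector(segs[[j]], k = k, collapse = collapse),
                          numeric(length(feats))))
  }
  splits <- do.call(rbind, rows)
  tnf <- do.call(rbind, tnfs)
  rownames(tnf) <- splits$split_name
  colnames(tnf) <- feats
  structure(
    list(splits = splits, tnf = tnf,
         params = list(split_target = split_target,
                       split_threshold = split_threshold,
                       k = k, collapse = collapse)),
    class = "contigs_table"
  )
}

#' @export
print.contigs_table <- function(x, ...) {
  cat("contigs_table:", nrow(x$splits), "splits from",
      length(unique(x$splits$parent)), "scaffolds;",
      ncol(x$tnf), "composition features (k =", x$params$k, ")\n")
  invisible(x)
}

#' Split names belonging to a set of scaffolds
#'
#' @param contigs A `contigs_table`.
#' @param scaffolds Character vector of scaffold names.
#' @return Character vector of split names, in contigs-table order.
#' @export
splits_of <- function(contigs, scaffolds) {
  contigs$splits$split_name[contigs$splits$parent %in% scaffolds]
}

#' Write the contigs table to TSV
#'
#' Writes one row per split with the descriptive columns followed by the
#' composition-feature columns, plus a sidecar `<path>.params.yaml`
#' recording the parameters used.
#'
#' @param contigs A `contigs_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_table <- function(contigs, path) {
  df <- cbind(contigs$splits, as.data.frame(contigs$tnf))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(contigs$params, paste0(path, ".params.yaml"))
  invisible(path)
}
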