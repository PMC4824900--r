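# Independent oracles and fixture builders shared across tests. These
# deliberately avoid the package's own k-mer / coverage code paths.

rand_seq <- function(n, p_n = 0) {
  letters <- c("A", "C", "G", "T")
  s <- sample(letters, n, replace = TRUE)
  if (p_n > 0) {
    idx <- which(runif(n) < p_n)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""),
         function(v) paste(rev(v), collapse = ""), character(1))
}

# brute-force canonical k-mer frequencies by explicit window enumeration
tnf_oracle <- function(s, k = 4) {
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
  all_k <- apply(g[, k:1, drop = FALSE], 1, paste, collapse = "")
  feats <- sort(unique(pmin(all_k, revcomp_chr(all_k))))
  out <- setNames(numeric(length(feats)), feats)
  n <- nchar(s)
  if (n < k) return(out)
  w <- substring(s, 1:(n - k + 1), k:n)
  w <- w[!grepl("[^ACGT]", w)]
  if (length(w) == 0) return(out)
  tb <- table(pmin(w, revcomp_chr(w)))
  out[names(tb)] <- tb / sum(tb)
  out
}

# brute-force per-base depth from 1-based positions and CIGAR strings
depth_oracle <- function(reflen, pos, cigar) {
  d <- integer(reflen)
  for (i in seq_along(pos)) {
    p <- pos[i]
    ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    for (op in ops) {
      len <- as.integer(sub(".$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        d[p:(p + len - 1)] <- d[p:(p + len - 1)] + 1L
        p <- p + len
      } else if (type %in% c("D", "N")) {
        p <- p + len
      }
    }
  }
  d
}

# write a sorted, indexed BAM from a read table; returns the BAM path
write_test_bam <- function(ref_lengths, reads, stem) {
  reads <- reads[order(match(reads$rname, names(ref_lengths)), reads$pos), ]
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths),
           sprintf("r%04d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                   seq_len(nrow(reads)), reads$flag, reads$rname,
                   reads$pos, reads$cigar))
  sam_path <- paste0(stem, ".sam")
  writeLines(sam, sam_path)
  Rsamtools::asBam(sam_path, stem, overwrite = TRUE)
}

# minimal contigs table skeleton (one split per scaffold) for tests that
# need only split names, parents and lengths
skeleton_contigs <- function(scaffolds, lengths) {
  splits <- data.frame(
    split_name = paste0(scaffolds, "_split_00001"), parent = scaffolds,
    start = 0, end = lengths, length = lengths, gc = 0.5,
    stringsAsFactors = FALSE)
  tnf <- matrix(1 / 136, nrow = length(scaffolds), ncol = 136,
                dimnames = list(splits$split_name, canonical_kmers(4)))
  structure(list(splits = splits, tnf = tnf,
                 params = list(split_target = 20000, split_threshold = 40000,
                               k = 4, collapse = TRUE)),
            class = "contigs_table")
}

# ground-truth skeleton for the SCG and coverage simulators
skeleton_truth <- function(n_host, n_contaminants, n_per_contaminant,
                           n_core = 3, n_aux = 6) {
  scaffolds <- c(sprintf("host_%04d", seq_len(n_host)),
                 if (n_contaminants > 0)
                   unlist(lapply(seq_len(n_contaminants), function(i)
                     sprintf("contaminant_%d_%04d", i,
                             seq_len(n_per_contaminant)))))
  source <- c(rep("host", n_host),
              if (n_contaminants > 0)
                rep(paste0("contaminant_", seq_len(n_contaminants)),
                    each = n_per_contaminant))
  contigs <- skeleton_contigs(scaffolds, rep(10000, length(scaffolds)))
  truth <- structure(list(
    scaffold_sources = data.frame(scaffold = scaffolds, source = source,
                                  stringsAsFactors = FALSE),
    split_sources = data.frame(split_name = contigs$splits$split_name,
                               source = source, stringsAsFactors = FALSE),
    libraries = rbind(
      data.frame(sample_id = sprintf("core_%02d", seq_len(n_core)),
                 kind = "dna", role = "core", aux_index = NA_integer_),
      data.frame(sample_id = sprintf("aux_%02d", seq_len(n_aux)),
                 kind = "dna", role = "aux", aux_index = seq_len(n_aux)),
      data.frame(sample_id = "rna", kind = "rna", role = "rna",
                 aux_index = NA_integer_))),
    class = "ground_truth")
  list(truth = truth, contigs = contigs)
}

write_tmp_tsv <- function(df, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
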