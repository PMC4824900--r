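#' Build the feature matrix used to organize splits
#'
#' In `combined` mode (the default organization) the matrix has a
#' composition block — the canonical k-mer frequencies as-is — and a
#' coverage block with one column per DNA library: `log10(mean_coverage
#' + 1)`, then min-max scaled to `[0, 1]` per column (a constant column
#' scales to all zeros), then globally reweighted by
#' `sqrt(n_composition_features / n_dna_samples)` so the two blocks carry
#' comparable aggregate weight under Euclidean distance. RNA libraries
#' are never used as clustering features. In `composition_only` mode
#' (second-pass curation) only the composition block is returned.
#'
#' @param contigs A `contigs_table`.
#' @param coverage A `coverage_set`, required for `combined` mode.
#' @param mode `"combined"` or `"composition_only"`.
#' @return A numeric matrix (rows = splits, in contigs order) with a
#'   `block` attribute tagging each column `"composition"` or
#'   `"coverage"`.
#' @export
build_feature_matrix <- function(contigs, coverage = NULL,
                                 mode = c("combined", "composition_only")) {
  mode <- match.arg(mode)
  comp <- contigs$tnf
  if (mode == "composition_only") {
    attr(comp, "block") <- rep("composition", ncol(comp))
    return(comp)
  }
  if (is.null(coverage)) stop("combined mode requires a coverage_set")
  dna <- coverage$samples$sample_id[coverage$samples$kind == "dna"]
  if (length(dna) == 0) stop("combined mode requires at least one DNA sample")
  covm <- coverage$mean[rownames(comp), dna, drop = FALSE]
  covm <- log10(covm + 1)
  covm <- apply(covm, 2, function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  })
  covm <- matrix(covm, nrow = nrow(comp),
                 dimnames = list(rownames(comp), paste0("cov_", dna)))
  covm <- covm * sqrt(ncol(comp) / length(dna))
  out <- cbind(comp, covm)
  attr(out, "block") <- c(rep("composition", ncol(comp)),
                          rep("coverage", ncol(covm)))
  out
}

#' Hierarchical clustering of splits
#'
#' Deterministic agglomerative clustering of the feature matrix, the
#' backbone along which bins are selected. Ward linkage on Euclidean
#' distance by default.
#'
#' @param matrix Feature matrix from [build_feature_matrix()] (>= 2 rows).
#' @param linkage `"ward"` (Ward's minimum variance, squared Euclidean
#'   updates), `"average"`, or `"complete"`.
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @return A `split_tree`: a rooted binary tree over the splits, wrapping
#'   the `hclust` object (merge heights give branch lengths).
#' @export
cluster_splits <- function(matrix, linkage = c("ward", "average", "complete"),
                           metric = "euclidean") {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  if (nrow(matrix) < 2) stop("clustering requires at least 2 splits")
  if (any(!is.finite(matrix))) stop("feature matrix contains non-finite values")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  hc <- hclust(dist(matrix, method = metric), method = method)
  structure(list(hclust = hc, linkage = linkage, metric = metric),
            class = "split_tree")
}

#' @export
print.split_tree <- function(x, ...) {
  cat("split_tree:", length(x$hclust$labels), "leaves (", x$linkage,
      "linkage,", x$metric, "distance )\n")
  invisible(x)
}

#' Cut a split tree into k clusters
#'
#' Removes the k - 1 highest merges; cluster ids are renumbered by first
#' appearance along the tree's leaf order, so id 1 is the leftmost clade.
#'
#' @param tree A `split_tree`.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector, split name -> cluster id.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "split_tree"))
  n <- length(tree$hclust$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  cl <- cutree(tree$hclust, k = k)
  leaf_order <- tree$hclust$labels[tree$hclust$order]
  first <- unique(cl[leaf_order])
  setNames(match(cl, first), names(cl))
}

quote_newick_label <- function(x) {
  bad <- grepl("[](),:;'\"\\[ \t]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Newick string for a split tree
#'
#' Branch lengths are derived from merge heights (leaves sit at height 0);
#' leaf names containing newick metacharacters are single-quoted.
#'
#' @param tree A `split_tree`.
#' @return A newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  hc <- tree$hclust
  labels <- quote_newick_label(hc$labels)
  n <- length(labels)
  if (n < 2) stop("tree must have at least 2 leaves")
  node_str <- character(n - 1)
  child <- function(j, parent_h) {
    if (j < 0) {
      sprintf("%s:%.10g", labels[-j], parent_h)
    } else {
      sprintf("%s:%.10g", node_str[j], parent_h - hc$height[j])
    }
  }
  for (i in seq_len(n - 1)) {
    h <- hc$height[i]
    node_str[i] <- paste0("(", child(hc$merge[i, 1], h), ",",
                          child(hc$merge[i, 2], h), ")")
  }
  paste0(node_str[n - 1], ";")
}

#' Export a split tree as a newick file
#'
#' @param tree A `split_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' Write the feature matrix in leaf order (for plotting)
#'
#' @param matrix Feature matrix from [build_feature_matrix()].
#' @param tree The `split_tree` clustered from it.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clustered_matrix <- function(matrix, tree, path) {
  ord <- tree$hclust$labels[tree$hclust$order]
  df <- data.frame(split_name = ord, matrix[ord, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
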