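# two-signature fixture: splits drawn from two divergent Markov chains
two_signature_contigs <- function(n_per = 20, len = 4000, seed = 77) {
  set.seed(seed)
  tm1 <- random_transition_matrix(2, divergence = 2)
  tm2 <- random_transition_matrix(2, divergence = 2)
  seqs <- c(
    vapply(seq_len(n_per), function(i)
      paste(c("A", "C", "G", "T")[
        scafscreen:::markov_sample_cpp(len, tm1, 2) + 1], collapse = ""),
      character(1)),
    vapply(seq_len(n_per), function(i)
      paste(c("A", "C", "G", "T")[
        scafscreen:::markov_sample_cpp(len, tm2, 2) + 1], collapse = ""),
      character(1)))
  asm <- Biostrings::DNAStringSet(seqs)
  names(asm) <- sprintf("g%d_sc%02d", rep(1:2, each = n_per),
                        rep(seq_len(n_per), 2))
  list(contigs = make_contigs(asm), labels = rep(1:2, each = n_per))
}

coverage_fixture <- function(ct, values, ids = names(values), kinds = NULL) {
  if (is.null(kinds)) kinds <- rep("dna", length(values))
  profs <- lapply(seq_along(values), function(i) {
    df <- data.frame(split_name = ct$splits$split_name,
                     mean_coverage = values[[i]],
                     detection = pmin(1, 1 - exp(-values[[i]])))
    profile_table(write_tmp_tsv(df), ct, ids[i], kinds[i])
  })
  merge_profiles(profs, ct)
}

test_that("feature matrix blocks follow the documented normalization", {
  ct <- skeleton_contigs(c("a", "b", "c"), rep(4000, 3))
  ct$tnf[] <- matrix(runif(3 * 136), nrow = 3)
  ct$tnf <- ct$tnf / rowSums(ct$tnf)
  rownames(ct$tnf) <- ct$splits$split_name

  comp <- build_feature_matrix(ct, mode = "composition_only")
  expect_equal(ncol(comp), 136)
  expect_true(all(attr(comp, "block") == "composition"))

  cov <- coverage_fixture(ct, list(s1 = c(0, 9, 99), s2 = c(5, 5, 5)))
  fm <- build_feature_matrix(ct, cov, "combined")
  expect_equal(ncol(fm), 138)
  w <- sqrt(136 / 2)
  # log10(x + 1) of {0, 9, 99} is {0, 1, 2}; min-max then scales to {0, .5, 1}
  expect_equal(unname(fm[, "cov_s1"]), c(0, 0.5, 1) * w)
  # constant column min-max scales to zeros
  expect_equal(unname(fm[, "cov_s2"]), c(0, 0, 0))
})

test_that("combined mode requires DNA coverage and RNA is never a feature", {
  ct <- skeleton_contigs(c("a", "b"), c(4000, 4000))
  expect_error(build_feature_matrix(ct, NULL, "combined"), "coverage")
  rna_only <- coverage_fixture(ct, list(r = c(1, 2)), kinds = "rna")
  expect_error(build_feature_matrix(ct, rna_only, "combined"),
               "DNA sample")
  both <- coverage_fixture(ct, list(d = c(1, 2), r = c(9, 9)),
                           kinds = c("dna", "rna"))
  fm <- build_feature_matrix(ct, both, "combined")
  expect_equal(colnames(fm)[137], "cov_d")
  expect_equal(ncol(fm), 137)
})

test_that("clustering merges identical rows first and builds a full tree", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  tr <- cluster_splits(m)
  expect_equal(nrow(tr$hclust$merge), 2)
  expect_setequal(tr$hclust$labels[-tr$hclust$merge[1, ]], c("a", "b"))
  expect_error(cluster_splits(m[1, , drop = FALSE]), "at least 2")
})

test_that("two composition signatures are recovered exactly at k = 2", {
  skip_if_not_installed("mclust")
  fx <- two_signature_contigs()
  fm <- build_feature_matrix(fx$contigs, mode = "composition_only")
  tr <- cluster_splits(fm)
  cl <- cut_tree(tr, 2)
  expect_equal(mclust::adjustedRandIndex(cl, fx$labels), 1)
})

test_that("cut_tree spans the whole range of k and orders ids by leaf order", {
  set.seed(13)
  m <- matrix(rnorm(40), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  tr <- cluster_splits(m)
  expect_equal(unname(cut_tree(tr, 1)), rep(1L, 8))
  expect_equal(sort(unname(cut_tree(tr, 8))), 1:8)
  expect_error(cut_tree(tr, 0))
  expect_error(cut_tree(tr, 9))
  cl <- cut_tree(tr, 3)
  leaf_order <- tr$hclust$labels[tr$hclust$order]
  expect_equal(unique(unname(cl[leaf_order])), 1:3)
})

test_that("clustering is invariant to row and within-block column order", {
  set.seed(17)
  m <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  coph <- function(tr) {
    d <- as.matrix(stats::cophenetic(tr$hclust))
    d[order(rownames(d)), order(colnames(d))]
  }
  base <- coph(cluster_splits(m))
  expect_equal(coph(cluster_splits(m[sample(10), ])), base)
  expect_equal(coph(cluster_splits(m[, sample(6)])), base)
})

test_that("composition_only mode ignores coverage entirely", {
  fx <- two_signature_contigs(n_per = 6, len = 2000, seed = 3)
  ct <- fx$contigs
  set.seed(4)
  cov1 <- coverage_fixture(ct, list(s = runif(nrow(ct$splits), 0, 50)))
  fm1 <- build_feature_matrix(ct, cov1, "composition_only")
  cov2 <- coverage_fixture(ct, list(s = runif(nrow(ct$splits), 0, 50)))
  fm2 <- build_feature_matrix(ct, cov2, "composition_only")
  expect_identical(to_newick(cluster_splits(fm1)),
                   to_newick(cluster_splits(fm2)))
})

test_that("newick export matches a hand-computed linkage and round-trips", {
  # three 1-d points 0, 1, 5 under average linkage: (a,b) merge at height 1,
  # then c joins at mean(5, 4) = 4.5
  m <- matrix(c(0, 1, 5), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  tr <- cluster_splits(m, linkage = "average")
  expect_identical(to_newick(tr), "(c:4.5,(a:1,b:1):3.5);")

  # two leaves
  m2 <- matrix(c(0, 2), ncol = 1, dimnames = list(c("A", "B"), NULL))
  ph <- ape::read.tree(text = to_newick(cluster_splits(m2)))
  expect_setequal(ph$tip.label, c("A", "B"))
  expect_equal(sum(ph$edge.length), 4)

  # write -> read -> write idempotence on random trees
  set.seed(19)
  for (i in 1:3) {
    mm <- matrix(rnorm(24), nrow = 8,
                 dimnames = list(sprintf("sp%02d", 1:8), NULL))
    tr <- cluster_splits(mm)
    f <- tempfile(fileext = ".nwk")
    export_newick(tr, f)
    ph1 <- ape::read.tree(f)
    ph2 <- ape::read.tree(text = ape::write.tree(ph1))
    expect_true(ape::all.equal.phylo(ph1, ph2))
    # leaf-to-leaf path length is twice the hclust merge height
    expect_equal(as.matrix(ape::cophenetic.phylo(ph1))["sp01", "sp02"],
                 as.matrix(stats::cophenetic(tr$hclust))["sp01", "sp02"] * 2,
                 tolerance = 1e-6)
  }
})

test_that("leaf names with metacharacters are quoted and survive reading", {
  m <- matrix(c(0, 1, 5), ncol = 1,
              dimnames = list(c("a(1)", "b:2", "plain"), NULL))
  tr <- cluster_splits(m)
  ph <- ape::read.tree(text = to_newick(tr))
  expect_length(ph$tip.label, 3)
  # ape keeps the quotes verbatim; the labels survive intact inside them
  expect_setequal(gsub("^'|'$", "", ph$tip.label),
                  c("a(1)", "b:2", "plain"))
})
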