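# a small assembly with one 3-split scaffold, one 2-split scaffold, and two
# unsplit scaffolds (splitting forced by a tiny split_target)
binning_fixture <- function(seed = 55) {
  set.seed(seed)
  seqs <- c(sc3 = rand_seq(3000), sc2 = rand_seq(2000),
            scA = rand_seq(1000), scB = rand_seq(1000))
  asm <- Biostrings::DNAStringSet(seqs)
  ct <- make_contigs(asm, split_target = 1000, split_threshold = 1000)
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(asm, fa)
  list(asm = asm, contigs = ct, fasta = fa)
}

simple_coverage <- function(ct, det_by_sample) {
  profs <- lapply(names(det_by_sample), function(id) {
    v <- det_by_sample[[id]]$det
    kind <- det_by_sample[[id]]$kind
    df <- data.frame(split_name = ct$splits$split_name,
                     mean_coverage = ifelse(v > 0, -log(1 - pmin(v, 0.999)), 0),
                     detection = v)
    profile_table(write_tmp_tsv(df), ct, id, kind)
  })
  merge_profiles(profs, ct)
}

test_that("load_selection validates names, conflicts and empty files", {
  fx <- binning_fixture()
  f <- tempfile()
  writeLines(character(0), f)
  expect_length(load_selection(f, fx$contigs), 0)

  all_splits <- fx$contigs$splits$split_name
  writeLines(c("split_name\tbin", paste(all_splits, "bin1", sep = "\t")), f)
  sel <- load_selection(f, fx$contigs)
  expect_length(sel, length(all_splits))

  writeLines(c(paste(all_splits[1], "A", sep = "\t"),
               paste(all_splits[1], "B", sep = "\t")), f)
  expect_error(load_selection(f, fx$contigs), "conflicting")

  writeLines("ghost_split\tA", f)
  expect_error(load_selection(f, fx$contigs), "unknown")
})

test_that("scaffolds resolve to bins by split-length majority", {
  fx <- binning_fixture()
  sp <- splits_of(fx$contigs, "sc3")
  sel <- as_bin_selection(setNames(c("A", "A", "B"), sp), fx$contigs)
  expect_equal(resolve_scaffolds(sel, fx$contigs), c(sc3 = "A"))

  sp2 <- splits_of(fx$contigs, "sc2")
  sel <- as_bin_selection(setNames(c("A", "B"), sp2), fx$contigs)
  expect_warning(out <- resolve_scaffolds(sel, fx$contigs), "tied")
  expect_length(out, 0)

  sel <- as_bin_selection(setNames("C", splits_of(fx$contigs, "scA")),
                          fx$contigs)
  expect_equal(resolve_scaffolds(sel, fx$contigs), c(scA = "C"))
})

test_that("bin reports conserve length and partition the RNA signal", {
  fx <- binning_fixture()
  ct <- fx$contigs
  n <- nrow(ct$splits)
  col <- scg_collection()
  hits <- scafscreen:::new_scg_hits(
    data.frame(gene = character(), split_name = character(),
               evalue = numeric()), 1e-10)
  # RNA detection x length mass of exactly 99 vs 1 between
  # {sc3, sc2} and {scA, scB}
  rna_det <- ifelse(ct$splits$parent %in% c("sc3", "sc2"),
                    99 / sum(ct$splits$length[ct$splits$parent %in%
                                                c("sc3", "sc2")]),
                    1 / sum(ct$splits$length[ct$splits$parent %in%
                                               c("scA", "scB")]))
  cov <- simple_coverage(ct, list(
    dna1 = list(det = rep(0.9, n), kind = "dna"),
    rna = list(det = rna_det, kind = "rna")))

  sel <- as_bin_selection(setNames(
    ifelse(ct$splits$parent %in% c("sc3", "sc2"), "big", "small"),
    ct$splits$split_name), ct)
  rep <- bin_report(sel, ct, cov, hits, col, rna_samples = "rna")
  expect_equal(rep$rna_recruitment[rep$bin == "big"], 0.99)
  expect_equal(rep$rna_recruitment[rep$bin == "small"], 0.01)
  expect_equal(sum(rep$rna_recruitment), 1)
  expect_equal(sum(rep$total_length), sum(Biostrings::width(fx$asm)))

  # everything in one bin recruits all the signal
  sel_all <- as_bin_selection(setNames(rep("only", n),
                                       ct$splits$split_name), ct)
  rep_all <- bin_report(sel_all, ct, cov, hits, col, rna_samples = "rna")
  expect_equal(rep_all$rna_recruitment[rep_all$bin == "only"], 1)

  expect_error(bin_report(sel, ct, cov, hits, col, rna_samples = "nope"),
               "absent")
})

test_that("annotation overlap is counted per bin over matched scaffolds", {
  fx <- binning_fixture()
  ct <- fx$contigs
  n <- nrow(ct$splits)
  col <- scg_collection()
  hits <- scafscreen:::new_scg_hits(
    data.frame(gene = character(), split_name = character(),
               evalue = numeric()), 1e-10)
  cov <- simple_coverage(ct, list(dna1 = list(det = rep(0.9, n),
                                              kind = "dna")))
  sel <- as_bin_selection(setNames(
    ifelse(ct$splits$parent == "sc3", "binA", "binB"),
    ct$splits$split_name), ct)
  expect_warning(
    rep <- bin_report(sel, ct, cov, hits, col,
                      annotations = c("sc3", "scA", "ghost")),
    "not in the assembly")
  expect_equal(rep$annotated_scaffolds[rep$bin == "binA"], 1)
  expect_equal(rep$annotated_fraction[rep$bin == "binB"], 0.5)
})

test_that("library-restriction flags follow the detection threshold rule", {
  ct <- skeleton_contigs(c("host1", "host2", "cont1", "none1"),
                         rep(5000, 4))
  cov <- simple_coverage(ct, list(
    core1 = list(det = c(0.9, 0.95, 0, 0), kind = "dna"),
    aux1 = list(det = c(0.8, 0, 0.9, 0), kind = "dna")))
  fl <- flag_library_restricted(cov, ct, "core1", "aux1")
  expect_equal(setNames(fl$flag, fl$scaffold),
               c(host1 = "core_supported", host2 = "core_supported",
                 cont1 = "aux_only", none1 = "undetected"))
  expect_error(flag_library_restricted(cov, ct, "core1", "core1"), "disjoint")
  expect_error(flag_library_restricted(cov, ct, "core1", "zzz"), "unknown")
})

test_that("export_bins writes whole scaffolds and conserves total length", {
  fx <- binning_fixture()
  ct <- fx$contigs
  sel <- as_bin_selection(setNames(
    ifelse(ct$splits$parent %in% c("sc3", "scA"), "keep", "drop"),
    ct$splits$split_name), ct)
  out <- tempfile()
  idx <- export_bins(sel, ct, fx$fasta, out)
  keep <- Biostrings::readDNAStringSet(file.path(out, "keep.fa"))
  expect_setequal(names(keep), c("sc3", "scA"))
  expect_identical(as.character(keep[["sc3"]]),
                   as.character(fx$asm[["sc3"]]))
  total <- sum(vapply(c("keep", "drop"), function(b)
    sum(Biostrings::width(
      Biostrings::readDNAStringSet(file.path(out, paste0(b, ".fa"))))),
    numeric(1)))
  expect_equal(total, sum(Biostrings::width(fx$asm)))
  expect_equal(sort(unique(idx$bin)), c("drop", "keep"))

  # a partially assigned selection exports the remainder as unassigned
  sel2 <- as_bin_selection(setNames("only", ct$splits$split_name[1]), ct)
  out2 <- tempfile()
  idx2 <- export_bins(sel2, ct, fx$fasta, out2)
  expect_setequal(
    names(Biostrings::readDNAStringSet(file.path(out2, "unassigned.fa"))),
    c("sc2", "scA", "scB"))
  expect_equal(sum(idx2$bin == "only"), 1)
  # missing scaffolds are an error
  bad_fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(fx$asm[1:2], bad_fa)
  expect_error(export_bins(sel, ct, bad_fa, tempfile()), "missing")
})
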