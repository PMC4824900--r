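#' Default simulation configuration
#'
#' Parameters of the bundled contaminated-assembly simulator. The default
#' scenario is one large host genome plus three complete bacterial
#' contaminant genomes whose reads appear only in a subset of the
#' auxiliary (long-read-style) libraries, while the host is sequenced in
#' every library; RNA signal is restricted to the host.
#'
#' @param seed Integer seed driving every random draw.
#' @param host_length Host genome size in bases (default 2e6).
#' @param n_contaminants Number of complete contaminant genomes (default 3).
#' @param contaminant_lengths Genome sizes in bases (default 5e5 each).
#' @param markov_order Order of the nucleotide Markov chains used as
#'   composition signatures (default 2).
#' @param composition_divergence Controls how far apart genome signatures
#'   are: transition-matrix rows are drawn Dirichlet with concentration
#'   `1 / composition_divergence`, so larger values give more divergent
#'   composition (default 1).
#' @param n_core_libraries Short-read-style libraries covering the host
#'   and (by default) no contaminant (default 3).
#' @param n_aux_libraries Long-read-style libraries; each contaminant is
#'   covered by a round-robin subset of these (default 6).
#' @param host_depth,contaminant_depth Intended mean per-base coverage of
#'   host (in every DNA library) and of each contaminant (in the
#'   libraries of its pattern); defaults 30 and 20.
#' @param contaminant_library_pattern Optional list, one integer vector
#'   per contaminant, of aux-library indices where it is present; NULL
#'   assigns aux libraries round-robin so patterns differ between
#'   contaminants.
#' @param coverage_noise_cv Coefficient of variation of the lognormal
#'   per-split depth noise (default 0.25).
#' @param scg_noise_rate Expected spurious host hits per single-copy gene
#'   (default 0.05).
#' @param rna_host_detection Target RNA detection on host splits
#'   (default 0.9).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              host_length = 2e6,
                              n_contaminants = 3L,
                              contaminant_lengths = rep(5e5, n_contaminants),
                              markov_order = 2L,
                              composition_divergence = 1,
                              n_core_libraries = 3L,
                              n_aux_libraries = 6L,
                              host_depth = 30,
                              contaminant_depth = 20,
                              contaminant_library_pattern = NULL,
                              coverage_noise_cv = 0.25,
                              scg_noise_rate = 0.05,
                              rna_host_detection = 0.9) {
  stopifnot(host_length > 0, n_contaminants >= 0,
            length(contaminant_lengths) == n_contaminants,
            all(contaminant_lengths > 0),
            markov_order >= 1, composition_divergence > 0,
            n_core_libraries >= 0, n_aux_libraries >= 0,
            host_depth >= 0, contaminant_depth >= 0,
            coverage_noise_cv >= 0, scg_noise_rate >= 0,
            rna_host_detection >= 0, rna_host_detection <= 1)
  if (is.null(contaminant_library_pattern) && n_contaminants > 0) {
    if (n_aux_libraries == 0) stop("contaminants require aux libraries")
    contaminant_library_pattern <- lapply(seq_len(n_contaminants), function(i) {
      which((seq_len(n_aux_libraries) - i) %% n_contaminants == 0)
    })
  }
  structure(list(
    seed = as.integer(seed), host_length = host_length,
    n_contaminants = as.integer(n_contaminants),
    contaminant_lengths = contaminant_lengths,
    markov_order = as.integer(markov_order),
    composition_divergence = composition_divergence,
    n_core_libraries = as.integer(n_core_libraries),
    n_aux_libraries = as.integer(n_aux_libraries),
    host_depth = host_depth, contaminant_depth = contaminant_depth,
    contaminant_library_pattern = contaminant_library_pattern,
    coverage_noise_cv = coverage_noise_cv,
    scg_noise_rate = scg_noise_rate,
    rna_host_detection = rna_host_detection
  ), class = "sim_config")
}

#' Random Markov transition matrix
#'
#' Rows are drawn independently from a symmetric Dirichlet with
#' concentration `1 / divergence`: small divergence gives near-uniform
#' (hence mutually similar) signatures, large divergence gives extreme,
#' well-separated ones.
#'
#' @param order Markov order k (matrix is `4^k x 4`).
#' @param divergence Positive scalar, see [simulation_config()].
#' @return Row-stochastic matrix.
#' @export
random_transition_matrix <- function(order = 2L, divergence = 1) {
  stopifnot(order >= 1, divergence > 0)
  n <- 4L^order
  g <- matrix(stats::rgamma(n * 4L, shape = 1 / divergence), nrow = n) + 1e-12
  g / rowSums(g)
}

#' Generate a genome as a set of scaffolds from a Markov composition model
#'
#' Emits 10-200 scaffolds with lognormally distributed relative lengths
#' summing exactly to `length`, each sampled from the given order-k
#' nucleotide transition matrix, so the whole genome carries one
#' composition signature.
#'
#' @param length Total genome size in bases.
#' @param transition_matrix `4^k x 4` row-stochastic matrix (rows indexed
#'   by the base-4 code of the k preceding bases, A=0 ... T=3).
#' @param seed Optional seed (NULL continues the current RNG stream).
#' @param prefix Scaffold name prefix.
#' @param length_sdlog sdlog of the lognormal scaffold-length weights
#'   (default 0.8).
#' @param min_scaffold Minimum scaffold length in bases (default 1200, so
#'   every scaffold survives the default profiling filter).
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(length, transition_matrix, seed = NULL,
                            prefix = "scaffold", length_sdlog = 0.8,
                            min_scaffold = 1200) {
  stopifnot(length >= 10 * min_scaffold, ncol(transition_matrix) == 4)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-8) ||
      any(transition_matrix < 0)) {
    stop("transition_matrix rows must be non-negative and sum to 1")
  }
  k <- round(log(nrow(transition_matrix), 4))
  if (4^k != nrow(transition_matrix)) {
    stop("transition_matrix must have 4^k rows")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- max(10L, min(200L, as.integer(round(length / 30000))))
  w <- rlnorm(n, meanlog = 0, sdlog = length_sdlog)
  len <- round(w / sum(w) * length)
  len <- pmax(len, min_scaffold)
  len[which.max(len)] <- len[which.max(len)] + (length - sum(len))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(len, function(L) {
    paste(bases[markov_sample_cpp(as.integer(L), transition_matrix, k) + 1L],
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_%04d", prefix, seq_len(n))
  out
}

#' Simulate per-library coverage profiles
#'
#' For every library and split, the mean coverage is drawn lognormally
#' around the intended depth of the split's source in that library (cv =
#' `coverage_noise_cv`), or is exactly 0 where the source is absent.
#' Detection follows the Poisson-coverage approximation
#' `1 - exp(-mean_coverage)` (depth 1 detects ~63% of positions), clipped
#' to `[0, 1]` and 0 at depth 0.
#'
#' @param truth A `ground_truth` (see [generate_dataset()]); only its
#'   `split_sources` and `libraries` components are used.
#' @param contigs The `contigs_table` of the simulated assembly.
#' @param config A `sim_config`.
#' @return List of `sample_profile` objects, DNA libraries then RNA.
#' @export
generate_coverage <- function(truth, contigs, config) {
  sp <- contigs$splits
  src <- truth$split_sources$source[match(sp$split_name,
                                          truth$split_sources$split_name)]
  if (anyNA(src)) stop("split_sources does not cover all splits")
  cv <- config$coverage_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(depth) {
    mc <- ifelse(depth > 0,
                 rlnorm(length(depth), meanlog = log(pmax(depth, 1e-12)) -
                          sdlog^2 / 2, sdlog = sdlog),
                 0)
    det <- pmin(pmax(1 - exp(-mc), 0), 1)
    det[mc == 0] <- 0
    list(mc = mc, det = det)
  }
  libs <- truth$libraries
  profiles <- vector("list", nrow(libs))
  for (i in seq_len(nrow(libs))) {
    lib <- libs[i, ]
    if (lib$kind == "rna") {
      det <- ifelse(src == "host",
                    pmin(pmax(config$rna_host_detection +
                                stats::rnorm(length(src), 0, 0.02), 0.05),
                         0.999),
                    0)
      mc <- ifelse(det > 0, -log(1 - det), 0)
      d <- list(mc = mc, det = det)
    } else {
      depth <- numeric(length(src))
      depth[src == "host"] <- config$host_depth
      for (ci in seq_len(config$n_contaminants)) {
        present <- lib$role == "aux" &&
          lib$aux_index %in% config$contaminant_library_pattern[[ci]]
        if (present) {
          depth[src == paste0("contaminant_", ci)] <- config$contaminant_depth
        }
      }
      d <- draw(depth)
    }
    profiles[[i]] <- new_sample_profile(
      data.frame(split_name = sp$split_name, mean_coverage = d$mc,
                 detection = d$det, stringsAsFactors = FALSE),
      sample_id = lib$sample_id, kind = lib$kind)
  }
  profiles
}

#' Simulate a single-copy-gene hit table
#'
#' Each contaminant genome, being complete, contributes exactly one hit
#' per collection gene, placed on a uniformly chosen split of that
#' genome; the host contributes Poisson(`scg_noise_rate`) spurious hits
#' per gene on random host splits. All e-values are drawn below the
#' default significance cutoff.
#'
#' @param truth A `ground_truth` with `split_sources`.
#' @param collection An `scg_collection`.
#' @param config A `sim_config`.
#' @return An `scg_hits` table.
#' @export
generate_scg_hits <- function(truth, collection, config) {
  ss <- truth$split_sources
  genes <- as.character(collection)
  rows <- list()
  for (ci in seq_len(config$n_contaminants)) {
    splits <- ss$split_name[ss$source == paste0("contaminant_", ci)]
    if (length(splits) == 0) stop("contaminant ", ci, " has no splits")
    rows[[length(rows) + 1L]] <- data.frame(
      gene = genes,
      split_name = splits[sample.int(length(splits), length(genes),
                                     replace = TRUE)],
      stringsAsFactors = FALSE)
  }
  host_splits <- ss$split_name[ss$source == "host"]
  if (config$scg_noise_rate > 0 && length(host_splits) > 0) {
    nhits <- rpois(length(genes), config$scg_noise_rate)
    if (sum(nhits) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = rep(genes, nhits),
        split_name = host_splits[sample.int(length(host_splits), sum(nhits),
                                            replace = TRUE)],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows) > 0) do.call(rbind, rows)
        else data.frame(gene = character(), split_name = character(),
                        stringsAsFactors = FALSE)
  df$evalue <- if (nrow(df) > 0) 10^runif(nrow(df), -40, -15) else numeric(0)
  new_scg_hits(df, evalue_max = 1e-10)
}

#' Generate a complete synthetic contaminated assembly
#'
#' Runs the whole simulator under one seed: divergent composition
#' signatures for host and contaminants, scaffold sets, the contigs
#' table, per-library DNA coverage (contaminants restricted to their aux
#' libraries), an RNA profile detecting only host scaffolds, a
#' single-copy-gene hit table, and ground-truth labels. When `out_dir`
#' is given, everything is also written as plain-text files (assembly
#' FASTA, one profile TSV per library, SCG hit TSV, truth TSV, config
#' YAML, manifest).
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `assembly` (DNAStringSet), `contigs`,
#'   `profiles` (list of `sample_profile`), `coverage` (`coverage_set`),
#'   `hits` (`scg_hits`), `truth` (`ground_truth`: `scaffold_sources`,
#'   `split_sources`, `libraries`), `config`, and `files` (named paths,
#'   when written).
#' @export
generate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sources <- c("host", if (config$n_contaminants > 0)
    paste0("contaminant_", seq_len(config$n_contaminants)))
  tms <- lapply(sources, function(s)
    random_transition_matrix(config$markov_order,
                             config$composition_divergence))
  names(tms) <- sources
  lens <- c(config$host_length, config$contaminant_lengths)
  genomes <- lapply(seq_along(sources), function(i)
    generate_genome(lens[i], tms[[i]], prefix = sources[i]))
  assembly <- do.call(c, genomes)
  scaffold_sources <- data.frame(
    scaffold = names(assembly),
    source = rep(sources, vapply(genomes, length, integer(1))),
    stringsAsFactors = FALSE)
  contigs <- make_contigs(assembly)
  split_sources <- data.frame(
    split_name = contigs$splits$split_name,
    source = scaffold_sources$source[match(contigs$splits$parent,
                                           scaffold_sources$scaffold)],
    stringsAsFactors = FALSE)
  libraries <- rbind(
    if (config$n_core_libraries > 0)
      data.frame(sample_id = sprintf("core_%02d",
                                     seq_len(config$n_core_libraries)),
                 kind = "dna", role = "core", aux_index = NA_integer_),
    if (config$n_aux_libraries > 0)
      data.frame(sample_id = sprintf("aux_%02d",
                                     seq_len(config$n_aux_libraries)),
                 kind = "dna", role = "aux",
                 aux_index = seq_len(config$n_aux_libraries)),
    data.frame(sample_id = "rna", kind = "rna", role = "rna",
               aux_index = NA_integer_))
  truth <- structure(list(scaffold_sources = scaffold_sources,
                          split_sources = split_sources,
                          libraries = libraries),
                     class = "ground_truth")
  profiles <- generate_coverage(truth, contigs, config)
  coverage <- merge_profiles(profiles, contigs)
  hits <- generate_scg_hits(truth, scg_collection(), config)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(assembly = file.path(out_dir, "assembly.fasta"))
    Biostrings::writeXStringSet(assembly, files[["assembly"]])
    for (p in profiles) {
      f <- file.path(out_dir, paste0("profile_", attr(p, "sample_id"), ".tsv"))
      write_coverage(p, f)
      files[paste0("profile_", attr(p, "sample_id"))] <- f
    }
    files["scg_hits"] <- file.path(out_dir, "scg_hits.tsv")
    write.table(as.data.frame(hits), files[["scg_hits"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    files["truth"] <- file.path(out_dir, "truth.tsv")
    write.table(scaffold_sources, files[["truth"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    files["config"] <- file.path(out_dir, "config.yaml")
    cfg <- config
    cfg$contaminant_library_pattern <-
      lapply(cfg$contaminant_library_pattern, as.integer)
    yaml::write_yaml(unclass(cfg), files[["config"]])
    files["manifest"] <- file.path(out_dir, "manifest.tsv")
    write.table(data.frame(name = names(files), path = unname(files)),
                files[["manifest"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(assembly = assembly, contigs = contigs, profiles = profiles,
                 coverage = coverage, hits = hits, truth = truth,
                 config = config, files = files))
}
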