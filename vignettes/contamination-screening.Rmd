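---
title: "Screening eukaryotic genome assemblies for bacterial contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening eukaryotic genome assemblies for bacterial contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafscreen)
```

## The problem

Eukaryotic genome assemblies are routinely contaminated by bacterial DNA —
from the sample itself, from extraction kits, or introduced during library
preparation. When multiple library preparations are co-assembled, each
preparation can contribute its own contaminants, and downstream analyses
(gene counts, claims of horizontal gene transfer) inherit the artifacts.
`scafscreen` applies the standard toolkit of metagenomic genome binning to
this curation problem: it treats the assembly as if it were a metagenome,
organizes its scaffolds by sequence composition and by differential
coverage across sequencing libraries, counts bacterial single-copy genes
to estimate how many complete bacterial genomes are hiding in the
assembly, and produces per-bin curation reports so contaminant bins can be
removed and the host draft genome exported.

## The workflow

The pipeline has four stages, mirroring the contigs-database /
per-library-profile / merge / bin-identification structure used by
metagenomic binning platforms.

**1. Contigs profiling** (`read_assembly()`, `make_contigs()`). Scaffolds
shorter than 1 kbp are dropped (their composition and coverage statistics
are too noisy to cluster). Scaffolds strictly longer than 40 kbp are cut
into `floor(L / 20000)` near-equal sections of at least 20 kbp each —
"splits" — so that one enormous scaffold contributes many observations
instead of one, and a chimeric scaffold can be recognized by its splits
disagreeing. For each split we record its length, GC-content (over
unambiguous bases only) and its tetranucleotide frequency (TNF) vector:
the frequencies of all 4-mers, computed over windows free of ambiguity
codes, with each 4-mer collapsed onto its reverse complement (the strand
of an assembled scaffold is arbitrary), giving 136 canonical features
that sum to 1. TNF is the classic composition signature: it is largely
conserved along a single genome and differs between unrelated genomes.

**2. Coverage profiling** (`profile_alignment()`, `profile_table()`). For
each sequencing library mapped to the scaffolds, each split gets its mean
per-base read depth and its *detection* — the breadth of coverage, i.e.
the fraction of positions covered by at least one read. All primary
alignments count regardless of pairing or mapping quality; secondary and
supplementary records are excluded (a flag re-enables them); deleted
reference positions (CIGAR `D`) contribute no depth. RNA-seq is profiled
by the identical code path; only its detection values are used
downstream, as a transcription indicator per split. A TSV entry point
(`profile_table()`) accepts precomputed per-split statistics, which is
also how the bundled simulator feeds the pipeline.

**3. Merging and clustering** (`merge_profiles()`,
`build_feature_matrix()`, `cluster_splits()`). Per-library profiles are
merged into splits-by-samples matrices, and splits are organized by
agglomerative hierarchical clustering of composition combined with
coverage. The combined feature matrix concatenates two blocks:

* the 136 TNF columns, used as-is (they are already frequencies on a
  common scale), and
* one column per DNA library of `log10(mean_coverage + 1)`, min–max
  scaled to [0, 1] per column, then multiplied by
  `sqrt(n_composition_features / n_dna_samples)`.

The log transform tames the heavy right tail of coverage; min–max puts
every library on the TNF scale; and the square-root-ratio weight makes
the two blocks contribute comparable aggregate variance under Euclidean
distance (Euclidean distance adds *squared* per-column differences, so
equalizing the column-count ratio requires the square root). Ward
linkage on Euclidean distance is the default; `average` and `complete`
are available. RNA libraries are never clustering features. A
`composition_only` mode re-clusters a selection on TNF alone, the usual
second pass when curating a bin whose coverage is uniform.

The tree is exported as newick (`export_newick()`), with merge heights as
branch lengths; `cut_tree(tree, k)` removes the k − 1 highest merges and
returns cluster memberships, the scriptable stand-in for selecting clades
interactively.

**4. Single-copy-gene census and curation** (`census()`, `bin_report()`).
Bacterial single-copy genes (SCGs) occur exactly once in nearly every
bacterial genome. Given an HMM search of the assembly against an SCG
collection (the bundled default is the 139-gene bacterial collection of
Campbell et al., shipped as a names file — run `hmmsearch` yourself and
feed the `--tblout` file to `parse_hmm_tblout()`), the census counts
significant hits per gene and takes the **mode** of that 139-long array
as the expected number of complete bacterial genomes: each complete
genome adds one hit to (almost) every gene, so G complete genomes push
the most common count to G, robustly to a few missing or duplicated
genes. Ties are resolved to the smallest tied value and flagged
`multimodal`, so contamination is never overstated. Per bin,
*completeness* (% of genes hit at least once) and *redundancy* (% hit
more than once) proxy bin completion and contamination.

`bin_report()` lifts a split-level selection to scaffolds (a scaffold
follows the bin holding the majority of its assigned split length; ties
are left unassigned with a warning) and reports, per bin: scaffold/split
counts, total length, length-weighted GC, per-library mean coverage and
detection, the SCG census, RNA recruitment, and overlap with an optional
external scaffold list (e.g. published HGT candidates).
`flag_library_restricted()` flags scaffolds detected (≥ `detection_min`,
default 0.5) only in auxiliary libraries — e.g. long-read preparations —
and in no core short-read library: genuine host scaffolds recruit reads
from every preparation of the same DNA, so aux-only detection is a strong
contamination signal. `export_bins()` writes whole original scaffolds
(never split fragments) per bin.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_length` | 1000 | bases | below this, TNF and detection are dominated by noise |
| `split_target` | 20000 | bases | section size balancing resolution vs statistic stability |
| `split_threshold` | 40000 | bases | strictly-greater cutoff; guarantees no split under 20 kbp |
| `k` | 4 | — | tetranucleotides: the standard compositional word size |
| `evalue_max` | 1e-10 | — | SCG hit significance cutoff, recorded in every report header |
| `detection_min` | 0.5 | fraction | a scaffold is "present" in a library when at least half of it is covered |
| `linkage` | ward | — | compact, deterministic clusters under Euclidean distance |

## The simulator

`generate_dataset()` builds a self-contained dataset with the
statistical structure the analysis assumes, plus ground-truth labels:

* **Composition.** Each genome (one host, `n_contaminants` bacteria) is
  emitted from its own order-2 nucleotide Markov chain. Transition-matrix
  rows are drawn Dirichlet with concentration
  `1 / composition_divergence`, so larger divergence yields more extreme,
  better-separated TNF signatures; the default (1) gives clearly distinct
  genomes, as unrelated bacteria and an animal genome would be. Genomes
  are emitted as 10–200 scaffolds with lognormal relative lengths
  (sdlog 0.8) summing exactly to the genome size, so some scaffolds
  exceed 40 kbp and exercise splitting.
* **Coverage.** Simulated at the profile level (no reads or BAMs): per
  split and library, mean coverage is lognormal around the intended depth
  (cv 0.25), and detection follows the Poisson-coverage approximation
  `1 − exp(−depth)` (depth 1 ⇒ ≈ 0.63). The host (depth 30) is present
  in every DNA library; each contaminant (depth 20) only in a
  round-robin subset of the auxiliary libraries, emulating
  library-preparation contamination that differs between preparations.
  A tiny programmatically written BAM exercises the alignment code path
  separately in the tests.
* **SCG hits.** Each contaminant, being complete, contributes exactly one
  hit per collection gene on a random split of its genome; the host adds
  Poisson(0.05) spurious hits per gene, emulating HMM profiles that are
  not perfectly bacteria-specific.
* **RNA.** Detection ≈ 0.9 on host splits, exactly 0 on contaminants.

Default scenario: host 2 Mbp, three contaminants of 0.5 Mbp, 3 core + 6
auxiliary DNA libraries, one RNA library — small enough that the whole
pipeline runs in seconds, large enough that every mechanism (splitting,
two-block clustering, census, flags) is exercised. Everything is
deterministic given the seed.

**What the simulator does not emulate:** read-level artifacts (sequencing
error, mapping ambiguity, repeats), within-genome composition
heterogeneity (a real genome is not a stationary Markov chain), chimeric
scaffolds, shared composition between related contaminants, splice-aware
RNA coverage, and partial bacterial genomes. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery
under the assumed signal structure, not performance on adversarial real
assemblies, where curation remains an iterative, judgment-laden process.

## Numerical and design notes

* Split remainders: `floor(L / target)` near-equal pieces (first
  `L mod n` pieces one base longer), so no piece is ever shorter than
  the target; coordinates are 0-based half-open, split ordinals 1-based
  in names.
* TNF windows containing any ambiguity code are skipped entirely — the
  simplest unbiased rule; reverse-complement collapsing can be disabled
  (`collapse = FALSE`, 256 features).
* Coverage columns that are constant min–max scale to all zeros rather
  than NaN.
* Merge-tie ordering inside the clustering is delegated to `hclust`,
  which is deterministic for fixed input order; the tests assert
  invariance of the tree's cophenetic structure to row and within-block
  column permutations.
* Mode ties in the census return the smallest tied value with a
  `multimodal` flag.
* RNA recruitment is computed as detection × length mass rather than raw
  read counts (read counts are not retained by the profiling contract);
  it is a proxy for "% of RNA reads recruited" and sums to 1 over
  bins ∪ unassigned whenever any signal exists.
* The 139 gene identifiers ship as a names file; any collection can be
  substituted via `scg_collection(path)` as long as the identifiers
  match the HMM output.

## Worked example

```{r example, eval = FALSE}
ds <- generate_dataset(simulation_config(seed = 1))
fm <- build_feature_matrix(ds$contigs, ds$coverage, "combined")
tree <- cluster_splits(fm)
cl <- cut_tree(tree, k = 4)
sel <- as_bin_selection(setNames(paste0("bin_", cl), names(cl)), ds$contigs)
bin_report(sel, ds$contigs, ds$coverage, ds$hits, scg_collection(),
           rna_samples = "rna")
```

On the default dataset this recovers the three planted bacterial genomes
as bins with 100% completeness and 0% redundancy, a host bin whose census
mode is 0, and contaminant bins recruiting none of the RNA signal; the
whole-assembly census mode equals 3, the number of planted genomes.

## Limitations

Bin selection here is `cut_tree()` plus selection files — there is no
interactive interface; real curation usually iterates between clustering
views. The SCG census assumes complete genomes: a half-genome shifts
counts but not necessarily the mode, so the estimate is of *complete*
bacterial genomes, a lower bound on contamination. Archaeal or eukaryotic
SCG collections are pluggable but not bundled. Equivalence with any
particular binning platform's tree layout is not claimed: normalization
and block weighting are documented choices, configurable where they
matter.
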