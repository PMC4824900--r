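Package: scafscreen
Title: Contamination Screening and Curation for Eukaryotic Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metagenomics-style screening of eukaryotic genome assemblies for
    bacterial contamination. Scaffolds are cut into fixed-size splits and
    profiled by GC-content, tetranucleotide frequency, and per-library mean
    coverage and detection (breadth of coverage); splits are organized by
    hierarchical clustering of composition combined with differential
    coverage across sequencing libraries; a bacterial single-copy-gene
    census estimates the number of complete bacterial genomes in an
    assembly or bin; and bin-level curation reports (length, GC, coverage,
    completeness/redundancy, RNA recruitment, library-restriction flags)
    support the removal of contaminant scaffolds. A bundled simulator
    generates contaminated assemblies with ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ape,
    ggplot2,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
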