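Package: capbias
Title: Allele-Specific Capture Bias in Hybrid Exome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying allele-specific
    hybridization-capture bias in F1 hybrid exome sequencing. Generates a pair
    of divergent parental genomes with a truth variant table, simulates
    single-end capture reads under a configurable allelic bias model plus a
    uniform whole-genome control, maps reads to both parental genomes with a
    seed-and-extend banded edit-distance aligner, assigns each read an allelic
    origin by edit distance, quantifies per-target log2 capture-bias ratios as
    a function of SNV and indel divergence, filters targets confounded by
    mapping bias via a two-strategy comparison, and measures heterozygous SNV
    detection sensitivity across sequencing depths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    stats,
    utils,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite
Config/testthat/edition: 3
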