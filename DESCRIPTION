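Package: chillomics
Title: Chromatin Accessibility, Transcriptional and Translational Responses
    to Chilling Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An integration pipeline for joint ATAC-seq, RNA-seq and
    Ribo-seq analysis of plants under chilling stress. Classifies genes by
    their joint transcriptional and translational response into five groups,
    computes translational efficiency from FPKM ratios, discovers and
    characterizes upstream open reading frames (uORFs) in 5' UTRs including
    base-pair-maximization folding energies, calls reproducible and
    cold-induced transposase hypersensitive sites (THSs) from replicate peak
    sets, assigns distal-site target genes, scans THS sequences with position
    weight matrices using exact score-distribution p-values, and builds a
    transcription-factor regulatory network. Ships a fully parameterized
    synthetic-data generator emulating the 3-replicate two-condition study
    design so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
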