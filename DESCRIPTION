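Package: lohtrack
Title: Loss-of-Heterozygosity Tract Calling and Concurrence Analysis in
    Paired Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls loss-of-heterozygosity (LOH) tracts from paired
    germline/tissue genotype tables by tracking heterozygote-to-homozygote
    transitions, stratified by copy-number state, with stringent and loose
    support criteria, marker-sparsity splitting and quality-control
    exclusion.  Detects concurrent LOH between two tissue samples of one
    patient, classifies overlap patterns (equal, single- or double-end
    extension, partial), and assesses concurrence against an
    arm-constrained permutation null.  Provides chromosome-arm LOH burden
    profiles, gene-level cross-patient concurrence tables, category
    enrichment tests, and a synthetic paired-cohort generator with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    IRanges,
    S4Vectors,
    generics,
    jsonlite,
    readr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
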