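Package: cardiogwas
Title: Quantitative Genetics of Cardiac Performance in Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for dissecting natural variation of cardiac
    performance traits in panels of sequenced inbred lines (DGRP-style designs).
    Derives per-fly cardiac traits from beat series, applies interquartile-range
    quality control, estimates variance components and broad-sense heritability,
    tests heterogeneity of within-line (micro-environmental) variance, runs
    linear mixed-model genome-wide association scans on line means and line CVe,
    performs focal-SNP pairwise epistasis scans, maps candidate variants to genes
    with transcription-unit and 1-kb promoter/terminator rules, computes
    hypergeometric gene-set enrichment and fly-to-human conservation tables, and
    discovers over-represented k-mers and position-specific scoring matrices in
    sequence windows around non-coding variants. A synthetic-panel simulator with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
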