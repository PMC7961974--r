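Package: somstrata
Title: Self-Organizing Map Portrayal and Molecular Subtype Discovery for
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Portrays bulk transcriptomes as self-organizing map (SOM)
    metagene landscapes and carries the analysis through to molecular
    subtypes: quantile normalization and gene centralization, batch SOM
    training with sample/group/difference portraits, segmentation of
    over-expression spot modules, correlation-silhouette class discovery,
    gene-set Z-score activity profiles, per-metagene ROC/AUC marker maps,
    constrained least-squares immune-cell deconvolution with LOESS
    trajectories along a tissue-gradient score, and a minimal pathway
    signal-flow engine.  Includes a seeded synthetic-cohort generator that
    emulates the statistical structure of a stratified biopsy study so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
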