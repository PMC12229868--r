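Package: npxnet
Title: Differential Abundance and Differential Co-Expression Networks for
    NPX Panel Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted panel immunoassay proteomics
    reported on the log2 NPX scale, motivated by synovial-fluid studies of
    knee osteoarthritis. Covers quality control of multi-dilution assay
    series (dilution selection within the dynamic range, dilution-linearity
    exclusion, limit-of-detection filtering), hierarchical linear
    mixed-model differential abundance with fold-change confidence
    intervals, all-pairs group-specific co-expression slopes via interaction
    regression with explicit network-edge selection rules, sparse
    group-specific Gaussian graphical models estimated by a fused joint
    graphical lasso (ADMM), and hypergeometric pathway over-representation
    against the detected-panel background. Includes a synthetic-data
    generator with known ground truth (planted effects, planted
    conditional-dependence edges, censoring, corrupted dilution series) so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    MASS,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
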