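Package: bzipspec
Title: Data-Driven Scoring and Design of bZIP Coiled-Coil Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and designs parallel bZIP coiled-coil dimer interactions
    from sequence. Registered coiled-coil dimers are encoded as sparse counts of
    structurally conserved residue pair and triplet contact types, and a linear
    additive scoring model on the log10 dissociation-constant scale is trained by
    semi-quantitative support vector regression, mixing two-sided
    epsilon-insensitive constraints for measured binders with one-sided
    constraints for censored non-binders. Includes dataset curation filters,
    similarity-aware balanced cross-validation partitioning, nested
    cross-validation with grid search, recursive feature elimination, and a
    combinatorial designer that assembles novel binders from native heptad
    modules by exact branch-and-bound under knowledge-based composition
    constraints and off-target specificity gaps. A synthetic-data generator
    emulates registered bZIP-like sequences and censored affinity measurements
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Matrix,
    jsonlite,
    Rcpp,
    methods,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    kernlab,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
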