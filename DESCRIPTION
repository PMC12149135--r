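Package: nmview
Title: Multi-View Prediction of RNA 2'-O-Methylation (Nm) Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA 2'-O-methylation (Nm) sites from 51-nt sequence
    windows by fusing three feature views: one-hot sequence encoding,
    nucleotide chemical properties, and a base-pair graph derived from the
    predicted secondary structure. The classifier combines convolutional
    branches for the sequence and chemical views, a multi-head graph
    attention network over the base-pair graph, and a cross-attention
    module that fuses sequence and structure representations, trained with
    binary cross-entropy and Adam. Ships the full evaluation protocol
    (stratified k-fold cross-validation, feature-view ablation, cross-subtype
    train/test matrix, per-position permutation importance), a synthetic
    benchmark generator with plantable sequence and structure signal, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
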