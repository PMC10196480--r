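Package: snfcca
Title: Prior-Guided Sparse Canonical Correlation Analysis for Imaging
    Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse canonical correlation analysis between an imaging
    quantitative-trait matrix and a genotype dosage matrix, with optional
    graph-Laplacian penalties that inject prior subject- or feature-level
    network structure (discriminative SCCA). Includes construction of the
    prior networks themselves: similarity network fusion of per-modality
    subject kernels by iterative cross-diffusion, diagnosis block networks,
    and gene co-expression networks aggregated to region level. A stratified
    nested cross-validation harness tunes the sparsity and prior-strength
    hyperparameters and reports fold-wise held-out canonical correlations
    and fold-averaged feature rankings. A synthetic cohort generator with
    planted sparse canonical structure makes every stage testable without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
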