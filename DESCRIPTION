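Package: micronet
Title: Sparse Inverse-Similarity Co-Occurrence Networks from Microbiome
    Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds taxon co-occurrence networks from metagenomic count
    tables.  Taxon-taxon similarity is measured nonparametrically, either by
    sin-transformed rank correlations (Spearman, Kendall tau-b) or by
    Gaussian kernels of ecological distances (Hellinger, chi-square,
    Bray-Curtis), and the network is the l1-penalised sparse inverse of the
    similarity matrix, so edges reflect partial (conditional) association
    rather than marginal correlation.  Includes StARS-style stability
    selection of the penalty over subsamples, modularity-based module
    detection by a two-phase local greedy algorithm, permutation tests for
    differential networks between clinical conditions, node-level network
    statistics, and a negative-binomial/Poisson count simulator with known
    precision structure for benchmarking edge recovery by ROC/AUC.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
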