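Package: spotweights
Title: Precision Weights for Spatially Variable Gene Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Removes the mean-variance bias in spatially resolved
    transcriptomics data. Estimates observation- and gene-level precision
    weights from the gene-wise mean-variance trend using per-gene
    nearest-neighbor Gaussian process fits and a smoothing-spline trend (a
    voom-style empirical-Bayes construction), and applies them via
    delta-method rescaling to produce weighted Gaussian-process
    likelihood-ratio rankings of spatially variable genes. Includes a
    Poisson log-Gaussian-process simulator with known ground truth, a
    Moran's I baseline ranker, and a decile-rank / FDR / TNR / TPR
    evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
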