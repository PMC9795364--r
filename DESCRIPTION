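Package: spotcorr
Title: Spatially Varying Gene-Gene Correlation Tests for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects spatially varying correlation structure within gene sets
    in spatial transcriptomics data. Provides a within-region test (WR-test)
    for smoothly varying gene-gene correlation inside a tissue region and a
    between-region test (BR-test) for correlation structure that differs
    between regions, both built on Gaussian-kernel estimates of spot-level
    means, variances and covariances and a multivariate-normal likelihood
    ratio statistic whose significance is assessed by sequential Monte Carlo
    permutation. Includes bootstrap confidence intervals for spot-level
    correlation estimates, clustering of gene-pair correlation patterns, a
    Poisson-lognormal simulator with Gaussian-process latent correlation
    fields for generating realistic spatial count data with known ground
    truth, and readers/writers for MatrixMarket, TSV and GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
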