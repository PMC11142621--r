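Package: fglinfer
Title: Fused Graphical Lasso Estimation and De-Biased Inference for
    Multiple Precision Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of several sparse Gaussian precision matrices
    with the fused graphical lasso (plain and weighted/correlation-scale
    variants), solved by an ADMM algorithm with an exact fused-lasso proximal
    operator.  De-biased (de-sparsified) entrywise estimators give
    asymptotically normal tests and confidence intervals for any linear
    combination of precision-matrix entries across groups, enabling
    differential-network analysis of, for example, gene-expression subtypes.
    Includes AIC tuning over a (lambda, rho) grid, a sparse precision-matrix
    simulator, and simulation harnesses for coverage and fluctuation
    (normality) experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
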