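Package: csde
Title: Corrected Sparse Density Estimation for Contaminated Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates an unknown univariate density as a sparse
    non-negative linear combination of known dictionary densities when the
    sample is contaminated by additive measurement error.  The corrected
    sparse density estimator (CSDE) minimizes an empirical L2-distance
    criterion under a weighted Elastic-net penalty whose l1 weights come
    from concentration inequalities and whose ridge term absorbs the
    measurement-error bias.  Includes the SPADES-style weighted-l1 and
    plain Lasso / Elastic-net baselines, an EM algorithm for mixture
    weights with fixed components, cross-validation by random dichotomy,
    KKT-based convergence diagnostics, and a simulation harness for
    contaminated Gaussian and overdispersed Poisson mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
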