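Package: hdeeg
Title: High-Dimensional Mean and Connectivity Change Tests for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical tools for detecting stimulus-induced changes in epoched
    multichannel time-series (EEG-style) data. Implements a ridge-regularized
    Hotelling T-squared test for equality of several high-dimensional mean
    vectors with a random-matrix (Stieltjes transform) plug-in calibration, a
    fused graphical lasso solved by an alternating direction method of
    multipliers for jointly estimating several sparse precision matrices, a
    de-biased entrywise z-test for linear combinations of precision matrices
    across populations, hyperparameter selection by AIC grid search or a
    data-driven learned rule, lasso-based channel screening, degree-centrality
    summaries of significant-change networks, and seeded generators for all of
    the simulation designs used to validate the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
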