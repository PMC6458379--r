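Package: glstrend
Title: Trend Significance in Small Datasets with Correlated Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized least-squares trend estimation and significance
    testing for small time-series and spatial datasets whose errors are
    serially or spatially correlated. Implements exact Durbin-Watson
    null moments with the beta-approximation test on raw and
    GLS-transformed residuals, four first-order autocorrelation
    estimators including a tanh-adjusted Durbin-Watson estimator with
    an extrapolated t-test for highly correlated small samples, the
    nearest-new-neighbour-path generalization of the Durbin-Watson
    statistic to scattered points in one to three dimensions with an
    exponential correlation model, semivariogram fitting, co-located
    observation handling, prediction intervals with design
    decorrelation, and seeded Monte Carlo harnesses for calibration,
    bias and trend-detection studies.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lmtest,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
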