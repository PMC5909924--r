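Package: nncox
Title: Neural-Network Cox Proportional-Hazards Regression for Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits feed-forward neural networks whose output layer is a Cox
    proportional-hazards regression, trained by maximizing a ridge- and
    dropout-regularized partial log-likelihood written in matrix form over a
    risk-set indicator matrix. Includes cross-validated hyperparameter search,
    survival accuracy metrics (Harrell's and IPCW concordance, dichotomized
    log-rank test, integrated Brier score), feature and hidden-node
    interpretation by partial derivatives, and a synthetic RNA-seq survival
    simulator with negative-binomial expression, Weibull event times and
    exponential censoring. Results are returned as tibbles with broom-style
    tidiers and ggplot2 plotting methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
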