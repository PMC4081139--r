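Package: predq
Title: Prediction Uncertainty Analysis for Dynamic Models via Posterior
    Parameter Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits ordinary differential equation models of biochemical
    dynamics to noisy time-series data by adaptive differential-evolution
    Markov chain Monte Carlo (DE-MCz), treats the resulting posterior
    parameter sample as a first-class, publishable artifact, and performs
    full computational prediction-uncertainty analysis: the dimensionless
    quantifier Q (time-averaged squared log-ratio between a predicted and
    a reference trajectory), its alpha-quantile Q_alpha, per-time-point
    prediction envelopes, qualitative-prediction statistics, systematic
    parameter-perturbation scans, and a linearized covariance analysis
    comparator based on local sensitivities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
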