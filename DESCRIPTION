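Package: cyclopop
Title: Population Pharmacokinetics and Bayesian Forecasting of Cyclosporine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling of
    cyclosporine from therapeutic drug monitoring (TDM) data. Implements a
    two-compartment disposition model with lagged first-order oral absorption
    (closed form plus a numerical-integration oracle), a log-normal
    inter-individual / inter-occasion variability model with a creatinine
    clearance covariate on apparent clearance, SAEM population estimation,
    importance-sampling log-likelihood and AIC, stepwise likelihood-ratio
    covariate selection, maximum a posteriori (MAP) empirical-Bayes estimation
    of individual parameters, sequential occasion-by-occasion Bayesian
    forecasting with rIPE/MPPE/rRMSE predictive-performance metrics, and
    simulation-based diagnostics (prediction-corrected visual predictive
    checks and normalized prediction distribution errors). Ships a synthetic
    cohort generator emulating a TDM study design so the full workflow is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
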