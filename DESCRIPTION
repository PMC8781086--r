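Package: mealsense
Title: Unannounced Meal Detection and Carbohydrate Estimation for
    Closed-Loop Insulin Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unannounced meals and estimates their carbohydrate
    content from continuous glucose monitor (CGM), insulin and meal time
    series, for use inside artificial-pancreas (closed-loop insulin
    delivery) systems.  A multitask sequence-to-sequence LSTM, trained
    with the pinball loss at the 2.5%, 50% and 97.5% quantiles, forecasts
    the last 20 minutes of the glucose trajectory with a 95% prediction
    interval; persistent excursions of the CGM above the upper bound
    while glucose rises at >= 1 mg/dL/min raise a meal flag, and an
    iterative inverse search over the meal input recovers the
    carbohydrate size.  The package ships a surrogate type 1 diabetes
    simulator (minimal-model glucose-insulin ODE with two-compartment
    gut and subcutaneous insulin absorption, behavioural meal
    announcement errors and CGM sensor noise), a generic basal-bolus
    closed-loop harness, and the usual evaluation layer: detection
    precision/recall/F-score with a 120-min matching window, time in
    range, blood-glucose risk indices and control-variability grid
    analysis (CVGA).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
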