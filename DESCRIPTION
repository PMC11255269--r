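Package: accvi
Title: Feedback-Driven Value Iteration Analysis for Go/No-Go Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of cortical
    populations recorded during go/no-go auditory discrimination tasks with
    manipulated stimulus-reward contingencies. Provides behavioral
    performance metrics (d-prime, phase splits), trial-aligned delta-F/F
    and z-score processing with responsiveness and onset screening,
    rule-based classification of outcome-monitoring, value-updating and
    dual-function neurons, population-trajectory geometry in principal
    component space with bootstrap resampling, cross-phase linear decoding,
    outcome-history regression, and a SARSA reinforcement-learning model
    with a trial-by-trial adaptive learning rate, together with a synthetic
    task and calcium-transient generator that provides full ground truth
    for validating every stage.
License: MIT + file LICENSE
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
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
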