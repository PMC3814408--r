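Package: bspcontrol
Title: Closed-Loop Estimation and Control of EEG Burst Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for brain-machine-interface control of medically-induced
    coma in simulation: segmentation of burst-suppression EEG into binary
    suppression events, recursive Bayesian estimation of the burst
    suppression probability (BSP) from binomial suppression counts with a
    two-compartment pharmacokinetic state model, nonlinear least-squares
    system identification from bolus responses, linear-quadratic-regulator
    and model-predictive anesthetic infusion controllers with input
    constraints, a closed-loop simulator with a surrogate-EEG generator,
    and steady-state performance metrics (MAD, MDPE, MDAPE), transition
    timing, and Beta-posterior reliability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
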