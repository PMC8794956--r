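Package: neuroinertia
Title: EEG-Based Quantification of Neural Inertia at Anesthetic Steady State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neural inertia -- the brain's path-dependent resistance
    to arousal-state transitions -- from murine EEG recorded at a steady
    anesthetic concentration. Implements the full analysis chain: EEG
    conditioning (decimation, zero-phase band-pass filtering, impedance-based
    channel exclusion, amplitude artifact masking, mean re-referencing), EMG
    movement detection by a log-RMS cumulative-distribution slope rule,
    multitaper spectral features over 4-s windows with principal-component
    reduction, ensembles of linear-discriminant and support-vector classifiers
    with a shuffled-label null, and balanced-accuracy hysteresis statistics
    with bootstrap, rank-based and ANOVA inference. A double-well Langevin
    simulator of stochastic anesthetic state switching generates synthetic
    cohorts with controlled inertia so the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    signal,
    withr,
    jsonlite,
    ggplot2,
    e1071,
    emmeans,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
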