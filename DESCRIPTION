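Package: auscultr
Title: Simulation and Rule-Based Detection of Adventitious Lung Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated classification of digital-stethoscope
    lung-sound recordings. Simulates study-shaped cohorts of posterior-thorax
    recordings with injected crackle and wheeze events under two device
    fidelity profiles, applies the standard normalization and Butterworth
    band-pass preprocessing chain, detects crackles and wheezes with
    rule-based waveform-morphology criteria (two-cycle and total duration for
    crackles; duration and dominant frequency for wheezes), converts
    detections to per-recording probability-style scores, and evaluates
    agreement against ground truth with positive/negative percent agreement,
    ROC threshold-interval optimization and Cohen's kappa, stratified by
    device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
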