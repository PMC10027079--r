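Package: somnarch
Title: Multilevel Analysis of Sleep EEG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A multilevel analysis pipeline for overnight sleep EEG
    (polysomnography-style) recordings: EDF input/output, referential
    derivations, zero-phase bandpass filtering and 30-second epoching;
    Welch power spectral density with log-log power-law slope, relative
    band power and an EEG/EOG slowing index; multiscale sample entropy;
    robust percentile features; wavelet-based sleep spindle detection and
    criterion-based slow-oscillation detection with per-event feature
    tables; macro sleep-architecture metrics from hypnograms; and
    multi-scorer/multi-device agreement statistics (Cohen's kappa,
    intraclass correlation, Mann-Whitney U, t-test, repeated-measures
    ANOVA). A seeded synthetic-night generator produces stage-labelled
    recordings with ground-truth spindle and slow-oscillation events so
    the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
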