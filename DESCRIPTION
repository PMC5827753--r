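Package: trusteeg
Title: EEG-Based Evaluation of Mentor-Trainee Trust in Robot-Assisted Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying a surgical mentor's trust in a trainee from
    the mentor's scalp EEG. Implements the full analysis pipeline: artifact
    masking and spectral preprocessing of multichannel EEG, closed-form
    cognitive features (mental load, situation awareness, blink rate, frontal
    alpha asymmetry, completion time), phase-locking-value functional
    connectivity aggregated into six-system strength and communication
    features, kernel-target-alignment feature ranking, linear support-vector
    trust classification under leave-one-out and 10-fold cross-validation,
    fuzzy C-means cluster validation, and group statistics. A synthetic-data
    module generates feature-level two-group datasets calibrated to published
    group summaries and signal-level coupled-oscillator EEG with ground-truth
    phase coupling, so the whole pipeline is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
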