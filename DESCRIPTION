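Package: squatfit
Title: Cardiorespiratory Fitness Prediction from Squat-Test Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a 45-second submaximal squat self-test of
    cardiorespiratory fitness. Reads and harmonizes tri-axial accelerometer
    recordings, extracts the motion-decay feature R_FSmax (the maximum of the
    unnormalized cross-correlation between two preprocessed windows of the
    acceleration magnitude), predicts peak oxygen uptake (VO2peak, L/min) with
    published regression models for healthy adults and coronary artery disease
    patients, and validates models by leave-one-subject-out cross-validation
    with Bland-Altman agreement statistics, partial correlations and
    fitness-category error breakdowns. Includes seeded generators for synthetic
    squat signals with parametric fatigue decay and synthetic cohorts, so the
    full pipeline is testable without access to study data.
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
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
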