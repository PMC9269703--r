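Package: bendr
Title: Movement Complexity and Classification Analysis of Instrumented
    Trunk Bending-and-Return Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for repetitive trunk bending-and-return
    tests recorded with three inertial measurement units (triaxial
    accelerometer + gyroscope at 100 Hz). Provides warm-up trimming and
    derived kinematic channels, Sample Entropy with lumbar and hip
    flexion complexity factors, movement-cycle segmentation with
    length-normalized cycles, statistical feature tables, group
    comparison statistics (SEM, confidence intervals, minimal detectable
    change), a repeated cross-validated benchmark of seven classifiers
    with grid search, sequential feature selection rankings, and a
    synthetic cohort generator with ground-truth cycle boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    pracma,
    e1071,
    rpart,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
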