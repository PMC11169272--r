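Package: carpe
Title: Stress-Test ECG Analysis and Collaborative Prediction of Functionally
    Relevant Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting functionally relevant coronary artery
    disease (fCAD) from exercise stress-test electrocardiograms and eight
    routine clinical variables. Implements the 2-6-2 summary-sequence
    construction, an ST-segment-depression baseline with QRS delineation, a
    multi-task residual convolutional network with auxiliary perfusion-score
    tasks, a collaborative logistic combiner that integrates the
    cardiologist's post-test probability, and a decision-analytic evaluation
    protocol (paired bootstrap, decision curves, net benefit, rule-out
    tables, calibration, subgroup interaction tests). Ships a synthetic
    stress-test cohort generator with exact fiducial and ST-offset ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    broom,
    dplyr,
    e1071,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
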