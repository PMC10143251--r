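Package: scdrowse
Title: Driver Drowsiness Detection from Wearable Skin-Conductance Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for detecting driver drowsiness from the
    electrodermal (skin conductance) signal of a wrist-worn device. Implements
    accelerometer-gated motion-artifact removal based on the stationary wavelet
    transform with Laplace-modelled coefficient thresholds, in both a
    non-overlapped segment variant and an improved overlapped variant that
    retains only the central part of each segment; linear oversampling;
    tonic/phasic (SCL/SCR) decomposition; fixed 15-second windowing with
    Karolinska Sleepiness Scale labelling; a 23-feature catalogue with Pearson
    correlation pruning; and a cross-validated ensemble classification harness
    (random forest, bagging, adaptive boosting). Includes a synthetic driving
    session generator so the whole pipeline is testable without recorded data.
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
    randomForest,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
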