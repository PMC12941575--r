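Package: gaitwarp
Title: Class-Selective Time-Warping Augmentation for Wearable Gait Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying physiology-informed, class-selective data
    augmentation in gait-pattern classification from multichannel wearable
    inertial signals. Provides a synthetic gait simulator with ground-truth
    stride events and class-differential variability structure, a fixed
    preprocessing and segmentation chain (resampling, Savitzky-Golay
    smoothing, Butterworth low-pass filtering, z-normalization, fixed-length
    windowing), smooth time-warping augmentation with Gaussian-perturbed
    knots applied selectively by class, Random-Forest channel ranking, a
    compact CNN-LSTM segment classifier, and an experiment harness that
    compares augmentation policies and sweeps augmentation intensity with
    ROC/AUC, confusion-matrix, and sample-entropy diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
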