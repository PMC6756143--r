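Package: apneanet
Title: Sleep Apnea Detection from Single-Lead ECG with a 1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep apnea from a single-lead electrocardiogram.
    Implements the full minute-by-minute pipeline: Hamilton-style R-peak
    detection, RR-interval and R-peak-amplitude series extraction with
    median-filter artifact correction, cubic-spline resampling of each
    labeled minute plus its two neighbouring minutes onto a uniform 900-point
    grid, a compact LeNet-style one-dimensional convolutional neural network
    classifier trained by backpropagation, a heart-rate-variability feature
    baseline (SVM, logistic regression, KNN, MLP), and per-segment /
    per-recording (apnea-hypopnea index) evaluation with recording-level
    cross-validation. A synthetic apnea-ECG simulator makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    glmnet,
    class,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
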