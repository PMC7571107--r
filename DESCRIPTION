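Package: ibistress
Title: Stress Classification from Inter-Beat-Interval Spatial and Frequency Domain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects acute psychological stress from photoplethysmogram-derived
    inter-beat intervals (IBIs). Sequences of beat durations are encoded as
    28x28 one-hot spatial images via distribution-based binning and a sliding
    window, optionally transformed to normalized log-magnitude 2-D Fourier
    (frequency-domain) images, and classified as stressed versus non-stressed
    with a deep convolutional neural network implemented in compiled code.
    Includes readers for Empatica E4-style IBI files, a synthetic multi-subject
    IBI cohort generator with controllable inter-subject heterogeneity, and
    evaluation harnesses for person-specific, generic (leave-subjects-out) and
    calibrated-generic experimental regimes with confusion-matrix metrics and
    stratified k-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
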