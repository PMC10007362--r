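Package: edanet
Title: Synthetic Electrodermal Activity and Fully Convolutional Stress
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates labeled electrodermal activity (EDA) traces as a sparse
    sudomotor spike train convolved with per-peak randomized Bateman
    (double-exponential) skin conductance response kernels, on top of a slowly
    varying tonic baseline with additive Gaussian noise.  The synthetic
    sequences train a one-dimensional fully convolutional network
    (conv/batch-norm/ReLU blocks, global average pooling, softmax) that
    classifies two-minute windows as neutral or active (stressed) arousal
    states without hand-engineered features.  Includes overlapping-window
    segmentation of long recordings, confusion-matrix/precision-recall
    evaluation, and an autoencoder reconstruction-error baseline showing why
    thresholding the mean absolute error fails to separate the two states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
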