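Package: scribbleprobe
Title: Content and Style Probing of Non-Figurative Drawings with
    Convolutional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying structured variation in non-figurative
    (scribble-like) drawings with a frozen VGG19-style convolutional
    backbone. Provides a seeded synthetic scribble generator with
    season-dependent palette, stroke-shape and coverage statistics; image
    standardization, NTSC grayscale conversion and coverage measurement; a
    transfer-learning classification head trained on frozen pooled
    features; layer-wise linear probing of activations (PCA to a target
    explained variance, then SVM with stratified 10-fold cross-validation)
    for RGB and grayscale inputs; Gram-matrix style probing of every
    convolutional layer; and the statistical comparison machinery (dummy
    baseline, 5x2cv paired t-test, one-sample t-test, accuracy-versus-depth
    slope regression) needed to compare probes against chance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
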