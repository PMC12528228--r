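Package: ecgception
Title: 1D Inception Networks for Multi-Label 12-Lead ECG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for multi-label classification of
    10-second 12-lead electrocardiograms: WFDB-dialect record input/output
    with Fourier-domain resampling, a one-dimensional Inception
    convolutional network trained with a differentiable double soft
    F1-loss, iterative multi-label stratified cross-validation, signal
    augmentation (additive noise, baseline wander), LIME surrogate
    explanations aggregated into a global class-by-lead importance matrix,
    and a seeded synthetic ECG generator with planted lead-localised class
    features for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
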