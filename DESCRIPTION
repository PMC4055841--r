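Package: mswld
Title: Multiscale Spatial Weber Local Descriptors for Mammographic Texture
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture characterization of mammographic regions of interest with
    the multiscale spatial Weber local descriptor (MSWLD): per-pixel
    differential excitation and quantized gradient orientation are binned into
    block-wise (T, M, S) histograms over square (P, R) neighborhoods and
    concatenated across blocks and scales. Includes a margin-based
    local-learning feature selector with cross-validated (sigma, lambda) grid
    search, an RBF-SVM classification harness with coarse-then-fine (C, gamma)
    tuning and stratified cross-validated evaluation (sensitivity,
    specificity, accuracy, ROC AUC), and a deterministic two-class synthetic
    ROI generator (mass-like vs parenchyma-like texture) so the full
    false-positive-reduction pipeline is testable without access to clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    EBImage,
    png,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
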