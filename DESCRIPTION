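Package: focalseg
Title: Lung Focal-Opacity Segmentation and Benign/Malignant Classification
Version: 0.1.0
Authors@R: person("focalseg", "maintainers", email = "focalseg@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for lung nodule ("focal opacity") analysis
    on CT-like slice images: a compact encoder-decoder convolutional network
    for per-pixel nodule/background semantic segmentation, handcrafted
    featurization of segmented nodules (histograms of oriented gradients,
    local binary patterns, and convex-hull diameter), concatenation fusion,
    and a bank of classical classifiers benchmarked under stratified 10-fold
    cross-validation.  Includes a seeded phantom-slice generator so the whole
    pipeline is testable without any external imaging data, image readers for
    PNG/JPEG and single-frame CT DICOM, the standard five-score semantic
    segmentation metric suite (global/mean accuracy, mean/weighted IoU,
    boundary F1), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    quadprog,
    png,
    jpeg,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
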