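Package: microdet
Title: Micro-Scale Object Detection Toolkit for Dense Small Targets in
    Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting small, dense, partially overlapping plant
    targets in UAV imagery. Provides IoU box geometry, size-stratified
    anchor estimation by k-means clustering under the IoU distance, the
    CIoU/EIoU/Focal-EIoU bounding-box regression loss family, greedy
    non-maximum suppression and confidence-weighted box fusion (including
    fusion across multi-resolution inference passes), a compact trainable
    convolutional detector with an optional micro-scale (stride-4)
    detection head, PR-curve average-precision evaluation, and a synthetic
    dense-scene generator with tiling, blur filtering, augmentation and
    multi-resolution resampling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
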