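Package: fiberseg
Title: Axon and Myelin Segmentation and Morphometry for Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-based semantic segmentation of axons and myelin sheaths in
    electron-microscopy images using a fully specified encoder-decoder
    convolutional network, together with the surrounding pipeline: resolution
    normalisation, joint image/label data augmentation (including elastic
    deformation), overlap-tile inference with stitching, segmentation and
    object-detection metrics, and binned morphometric maps (equivalent axon
    diameter, density, axon/myelin volume fractions, aggregate g-ratio).
    A synthetic generator of myelinated-fiber images with exact ground truth
    makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
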