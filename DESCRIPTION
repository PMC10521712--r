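Package: joshuaseg
Title: Spatial Histogram UNET Models for Adipose Tissue Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoder-decoder convolutional networks for binary semantic
    segmentation of histology images, built around a learnable spatial
    histogram layer that carries statistical texture features across the
    skip connections of a UNET. Provides five comparison architectures
    (UNET, UNET+, attention UNET, JOSHUA, JOSHUA+) with concatenation and
    attention-inspired elementwise-multiplication fusion, a CPU training
    engine (Adam, weighted binary cross entropy, gradient clipping, early
    stopping), segmentation metrics, cross-validation fold schemes, a
    synthetic H&E-like image generator, and physical adipose-area
    quantification from microscope calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
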