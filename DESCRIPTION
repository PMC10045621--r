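Package: shearseg
Title: Shear-Transform Deformable U-Net Segmentation for Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semantic segmentation of 2-D grayscale ultrasound images with a
    U-Net variant in which every 3x3 convolution is replaced by a composite
    block: shear transform, deformable convolution with learned sampling
    offsets, and inverse shear transform. Includes exact and interpolated
    shear warps, a from-scratch deformable convolution with analytic
    gradients, the full encoder-decoder with ablation variants, a synthetic
    ultrasound-phantom generator with exact ground-truth masks (speckle,
    blurred boundaries, intensity inhomogeneity), Adam training with Dice and
    Jaccard evaluation, and a command-line interface for dataset generation,
    training, evaluation and prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
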