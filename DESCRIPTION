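Package: octseg
Title: Segmentation of 3D Optical Coherence Tomography Images of Thick Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for volumetric segmentation of optical
    coherence tomography (OCT) images of human thick skin into five
    structural classes (probe-gap background, upper stratum corneum,
    ordered stratum corneum, cellular epidermis, dermis). Provides a
    seeded speckle-phantom generator for layered skin, a semi-automatic
    statistical boundary-detection labeler, 2D and 3D U-Net
    encoder-decoder networks with a self-contained CPU training engine
    (Adam, cross-entropy), block-based inference with Gaussian-weighted
    confidence blending, Sorensen-Dice evaluation, and layer-thickness
    morphometry with refractive-index correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
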