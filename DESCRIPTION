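Package: dfirseg
Title: Label-Free Histopathology Segmentation from Discrete-Frequency
    Infrared and Darkfield Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for label-free digital histopathology of oral
    epithelial dysplasia from multimodal microscopy. Combines
    discrete-frequency infrared (DFIR) absorbance images at the Amide III,
    Amide II and Amide I bands (1238, 1546, 1658 cm-1) with darkfield
    visible images, normalizes the two fingerprint bands to Amide I to
    cancel thickness and density variation, and trains a fully
    convolutional network to segment tissue into non-epithelium,
    dysplastic epithelium and non-dysplastic epithelium. Includes a
    synthetic tissue-phantom generator with ground-truth labels so every
    stage is testable at desk scale, patch extraction with section-level
    splitting, a compiled training engine (Adam, stepped learning-rate
    schedule, early stopping, random affine augmentation, replicate
    training), tiled whole-section inference, and evaluation via
    row-normalized confusion matrices, overall accuracy and macro F1 with
    replicate mean and standard deviation, including a modality ablation
    (darkfield only, IR only, combined).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
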