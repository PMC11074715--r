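Package: contourtl
Title: Contour-Based Brain MRI Preprocessing and Transfer-Learning Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, reproducible pipeline for binary brain-tumor
    detection from 2-D MRI slices: largest-contour brain cropping (grayscale,
    Gaussian smoothing, binarization, morphological cleanup, external contour
    retrieval), grey-level-preserving threshold segmentation with an Otsu
    threshold selector, deterministic geometric augmentation plans,
    stratified and leakage-guarded train/validation/test partitioning, a
    VGG-16-style convolutional classifier with frozen feature layers and a
    fine-tuned head (implemented as a compact CNN engine over BLAS), and a
    seven-metric evaluation suite (sensitivity, specificity, precision, NPV,
    accuracy, F1, ROC-AUC) with a confusion-matrix reconstruction solver.
    Ships a synthetic phantom generator so the whole pipeline is testable
    without any external image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
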