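Package: fluidcam
Title: Retinal Fluid Visualization and Volumetry from OCT Class Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intraretinal fluid (IRF), subretinal fluid (SRF) and
    pigmented epithelial detachment (PED) in optical coherence tomography
    (OCT) C-scans from the visualization output of binary pathology
    classifiers rather than from a segmentation network. Provides a synthetic
    OCT phantom generator with gamma-distributed multiplicative speckle, a
    configurable Inception-ResNet-style classifier and a gated
    convolution-deconvolution despeckler built on a compact in-package CNN
    engine, five class activation mapping techniques (Grad-CAM, Grad-CAM++,
    Score-CAM, Ablation-CAM, Self-Matching-CAM) fused by majority-vote
    Ensemble-CAM, Otsu binarization, seeded region growing and selective
    thresholding refinement, and per-scan fluid volume computation with
    Jaccard/Dice and confusion-matrix evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    grDevices,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
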