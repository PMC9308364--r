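Package: oarseg
Title: Landmark-Guided Organ-at-Risk Autosegmentation and Contour Evaluation on Synthetic CT Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a landmark-guided deep image-to-image
    autosegmentation pipeline for radiotherapy organs at risk, exercised entirely on
    synthetic planning-CT-like phantoms with known ground truth. Provides a 3D volume
    and mask data model with world-coordinate resampling and cropping (LPS convention,
    NIfTI I/O), a seeded phantom generator with parametric organs and a controlled
    contour-perturbation model, a multi-scale agent that walks towards anatomical
    landmarks to define organ regions of interest, a convolutional encoder-decoder
    segmentation network with strided-convolution downsampling and trilinear upsampling,
    and the complete geometric contour-comparison formulary (volume, Dice, Jaccard,
    sensitivity, specificity, discordance, geographical miss, mean and residual-mean
    surface distance, Hausdorff distances, centroid distance, directional boundary
    differences) with cohort-level aggregation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
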