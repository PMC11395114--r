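Package: wormaging
Title: Well-Plate Imaging Pipeline for Biological Age Estimation in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end image analysis for single-worm aging studies in 384-well
    plates. Provides a seeded synthetic well-image generator with ground-truth
    masks, centerlines and survival records; classical preprocessing (median
    denoise, histogram equalization, 8-bit conversion); worm segmentation by
    inverted thresholding with morphological cleaning or by a trainable U-Net;
    centerline skeletonization, keypoint extraction and global orientation
    fitting; resampling of curved worms into canonical 600x30 straightened
    strips; a residual convolutional network (WormCNN) that classifies worms as
    elderly versus non-elderly and regresses biological age; Kaplan-Meier
    survival curves with a 20 percent-survival elderly threshold; and the
    Healthy Aging Index (HAI) report comparing predicted biological age with
    chronological age. All neural-network layers are implemented in-package
    (im2col convolution, batch normalization, residual blocks, Adam) so the
    pipeline runs on a plain CPU with no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    pROC,
    survival,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
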