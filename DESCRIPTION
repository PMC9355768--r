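Package: lesionfuse
Title: Fused Encoder-Decoder Segmentation of Skin Lesions in Dermoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for binary skin-lesion segmentation in dermoscopy images
    with a two-branch fused convolutional model. Implements a 2-D V-Net branch
    with residual stages and group normalization, a U-Net branch with residual
    blocks and batch normalization, a fused Dice plus Focal Tversky training
    loss, the accompanying preprocessing (piecewise-linear contrast stretch,
    unsharp-mask sharpening, resizing) and augmentation recipe (flips,
    rotation, grid distortion, elastic deformation, lesion-boundary crops),
    and overlap-based fusion of the two branch predictions with small
    connected-component removal. Includes a synthetic dermoscopy-like image
    generator so the full pipeline is testable at desk scale, overlap metrics
    (Dice, Jaccard, thresholded Jaccard, accuracy, sensitivity, specificity),
    and a compact CPU convolutional-network engine with reverse-mode
    gradients and ADAM optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
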