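Package: bbseg
Title: Trainable Pixel-Wise Image Segmentation with a Dual-Output CNN and
    Distance-Map Watershed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A no-code workflow for instance segmentation of raster images
    with touching regions. A small multi-scale convolutional neural network
    with two heads is trained on user-labeled example images to predict, for
    every pixel, (i) the probability of lying inside a region and (ii) the
    capped Euclidean distance to the nearest region edge. New images are then
    segmented by thresholding the probability map and splitting the foreground
    into distinct labeled regions with a seeded watershed on the predicted
    distance map, which separates regions in contact. Includes project
    scaffolding driven by a plain-text parameter file, class-balanced
    training-pixel subsampling, dihedral augmentation, SEG/Jaccard evaluation,
    and synthetic fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
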