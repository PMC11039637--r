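Package: lesionforge
Title: Sparrow-Search Optimised Encoder-Decoder Segmentation and
    Incremental Tree-CNN Classification for Dermoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dermoscopic skin-lesion analysis built around a
    fully convolutional encoder-decoder segmentation network (FCEDN)
    whose architecture is encoded as a flat 22-gene hyperparameter
    vector and tuned by the sparrow search algorithm maximising a
    smoothed Jaccard fitness.  Includes the accompanying preprocessing
    stack (bilinear resizing, colour-space conversion, contrast-limited
    adaptive histogram equalisation, adaptive median and adaptive local
    noise filters, morphological hair removal), pixel-level evaluation
    metrics (accuracy, sensitivity, specificity, precision, F1,
    Matthews correlation, Jaccard, Dice), an incrementally growable
    Tree-CNN classifier with label-transform bookkeeping, a seeded
    synthetic dermoscopy image generator, and an end-to-end pipeline
    driver.  All networks are trained with a small built-in
    RcppArmadillo convolution engine, so the package has no deep
    learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
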