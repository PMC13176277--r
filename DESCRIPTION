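Package: culmcount
Title: Tiller Counting from Top-Down Images by Edge-Based Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for counting grass tillers (clipped ~2 cm shoot segments
    spread on a dark background) in top-down RGB images. Provides a
    reproducible synthetic scene generator with exact bounding-box ground
    truth across density regimes; a classical edge-based segmentation
    counter (HSV hue thresholding, morphological erosion and Gaussian
    smoothing, Canny edge detection, dilation, connected-component
    analysis); detector-agnostic post-processing (confidence filtering,
    greedy non-maximum suppression, IoU matching, average precision at 50%
    IoU); label-preserving dataset augmentation with exact bounding-box
    bookkeeping; annotation readers and writers (LabelMe JSON, YOLO text,
    COCO JSON) with stratified dataset splitting; and an evaluation harness
    for predicted-versus-manual counts (R-squared, RMSE, NRMSE, MAPE, MAE,
    bias) stratified by tiller density, plus population-level distribution
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    grDevices,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    yaml
Config/testthat/edition: 3
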