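Package: rwgtsc
Title: Single-Cell Adhesion Kinetics and Time-Series Classification for
    Resonant Waveguide Grating Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for label-free resonant waveguide grating
    (RWG) biosensor recordings of single-cell adhesion: synthesis of
    ground-truthed wavelength-shift well videos, global background
    correction, 2D local-maxima cell detection, Voronoi region-of-interest
    partitioning and per-cell maxWS kinetic signal extraction; dataset
    construction with zero-offsetting, batch-artifact correction,
    fixed-length cuts, stratified k-fold splits, SMOTE class balancing and
    train-statistics standardization; six 1D convolutional/dense
    time-series classifiers (MLP, CNN, FCN, ResNet, MCDCNN, Inception)
    with cross-validated training, early stopping and confusion-matrix
    metrics; and grad-CAM interpretation of classifier decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
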