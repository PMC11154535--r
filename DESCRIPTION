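Package: cagemon
Title: Camera-Only Monitoring of Caged Animals from Behavior and Heart-Rate Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts behavioral features (movement, body-shape change,
    direction change) and an internal-state feature (a heart-rate proxy from
    green-channel micro-variation, i.e. video photoplethysmography) from
    top-view cage video of a single small animal, and flags non-routine
    states with a one-class support vector machine. Includes HSV
    color-threshold calibration and segmentation with a pluggable backend,
    PCA-based orientation estimation, Butterworth bandpass filtering with
    peak-interval heart-rate estimation, five-fold cross-validated parameter
    selection, baseline comparisons (two-class SVM, LDA, MLP), and a
    ground-truthed synthetic scene generator so the whole pipeline is
    testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    e1071,
    MASS,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
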