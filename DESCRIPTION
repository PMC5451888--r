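Package: grapedetect
Title: Robust Grape Berry Detection with Weighted Grayscale Conversion, HOG
    Features and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of white-variety grape berries in 40 x 40 pixel object
    images cut from vineyard photographs. The detector converts RGB input to
    grayscale with a tunable weighted mean of the colour channels, extracts a
    histogram-of-oriented-gradients (HOG) descriptor at a fixed configuration
    (9 unsigned bins, 6 x 6 px cells, 2 x 2 cell blocks with one-cell overlap)
    and classifies with a soft-margin support vector machine (linear or
    Gaussian kernel). The package implements the constrained simplex-grid
    tuning methodology for the conversion weights together with the SVM
    hyperparameters, anomaly filtering of degenerate kernel settings,
    priority-based selection among performance measures, ternary-diagram
    visualization of performance surfaces over the weight simplex, a synthetic
    vineyard scene generator, and rotation-augmented dataset construction for
    probing rotational robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    png,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
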