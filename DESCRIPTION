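Package: emflowtomo
Title: Electromagnetic Blood-Flow Tomography with Autoencoder-Augmented
    Neural Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates flow-induced electrode potentials on a parametric 2D
    neck phantom carrying a stenosed carotid artery in a uniform magnetic
    field, and reconstructs the axial blood-velocity image from the 11
    boundary potential differences. Provides the weight-function (reciprocity)
    forward model on a heterogeneous finite-difference grid, a convolutional
    auto-encoder that compresses the 11 x 2601 weight matrix into sub-feature
    matrices, the data-domain transformation that maps voltages into
    velocity-domain features, a reconstruction CNN, plus Tikhonov and
    fully-connected baselines, with RMSE/CC evaluation under clean and noisy
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    MASS,
    data.table,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
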