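Package: morphoflat
Title: Quantification of Morphogen Gradients in Curved Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packager", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify protein distributions (e.g. morphogen
    gradients) in flat and curved single-layer epithelia from multi-channel
    3D confocal stacks. The pipeline extracts the apical surface from a
    junctional marker channel, computationally flattens each x-z plane,
    crops a fixed-depth quantification band, reparameterizes intensity
    profiles by apical contour length, aligns per-plane profiles to a
    reference location (reporter sigmoid, fold center, or manual),
    subtracts controls, corrects for imaging depth, normalizes, and fits
    exponential, sigmoid and Gaussian models to estimate gradient decay
    rates, source-boundary locations, and mosaic clone positions. A
    synthetic stack generator with known ground truth supports end-to-end
    validation, and a minimal multi-page TIFF reader/writer plus a small
    command-line interface handle input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
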