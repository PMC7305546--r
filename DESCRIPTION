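Package: eitfat
Title: Abdominal Subcutaneous Fat Thickness Estimation by Absolute
    Electrical Impedance Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for estimating the
    thickness of abdominal subcutaneous fat from electrical impedance
    tomography (EIT) data. Provides a 2D finite-element forward solver
    for the generalized Laplace equation on disk, ellipse and
    abdomen-like domains with pairwise current-injection protocols; a
    geometry-dependency-reducing voltage normalization; a layered
    (fat/muscle/rest) conductivity model on distance-to-boundary
    layers; a synthetic training-set generator; a multilayer-perceptron
    inverse map fit by sum-of-squared-errors with full S3 modelling
    methods; and a Tikhonov-regularized least-squares baseline for
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
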