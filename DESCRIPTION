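Package: flowPhantom
Title: Digital Linear Conveyor-Belt Flow Phantom and Velocimetry for
    Retinal Blood-Flow Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A digital twin of a linear conveyor-belt flow phantom used to
    calibrate retinal blood-flow imaging instruments, together with the two
    velocimetry analyses used to validate such phantoms. The package models
    the phantom physics (DC-motor voltage to belt velocity, pulley
    kinematics, paraxial optics, stochastic bead monolayers), simulates
    adaptive-optics scanning laser ophthalmoscope (AO-SLO) line-scan
    space-time images and clinical-SLO indocyanine-green-angiography style
    frame videos of the moving bead field, and estimates velocity back from
    both data products: Radon-style streak-slope velocimetry with sec(alpha)
    vessel-angle correction on kymographs, and Laplacian-of-Gaussian spot
    detection with linear-assignment particle tracking on frame videos. A
    calibration workbench reproduces linearity, repeatability and
    vessel-angle sweep analyses entirely from synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'phantom-core.R'
    'render.R'
    'frame-sim.R'
    'lap.R'
    'tracking.R'
    'linescan-sim.R'
    'streaks.R'
    'calibration.R'
    'flowPhantom-package.R'
    'io.R'
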