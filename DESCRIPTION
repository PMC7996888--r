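Package: woundtrack
Title: Pseudo-Particle Tracking of Wound-Edge Dynamics in Phase-Contrast Time-Lapse Images
Version: 0.1.0
Authors@R: person("woundtrack", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for wound-healing scratch assays imaged in
    phase contrast. Frames are contrast-equalized (CLAHE), tiles are
    classified as cell layer or background from local-binary-pattern
    texture histograms via PCA and a two-component Gaussian mixture, the
    wound-edge polylines are extracted from the binary masks, and pseudo-
    particles placed at uniform arc length along each front yield
    single-particle-tracking statistics (ensemble means, velocity and
    acceleration series, autocorrelation, mean squared displacement),
    drift-velocity fits and velocity-increment distribution fits, plus a
    synthetic wound generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    png,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
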