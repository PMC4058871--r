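Package: magsep
Title: Magnetophoretic Bead Capture in Microchannels with Soft-Magnetic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Coupled Lagrangian-Eulerian simulation of magnetic bead capture in a
    2D microchannel containing magnetized rectangular soft-magnetic elements.
    Computes the closed-form magnetostatic field of rectangular elements under a
    uniform bias field, the effective-dipole magnetic force on superparamagnetic
    beads with a saturating magnetization model, steady incompressible laminar
    flow around flow-invasive obstacles on a staggered finite-volume grid, and
    Lagrangian parcel tracking under Stokes drag with optional two-way
    particle-fluid momentum coupling. Reports capture efficiency and retention
    statistics for wall-embedded and flow-invasive stair-step element arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
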