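Package: mesopaint
Title: Headless 2.5D Mesoscale Scene Construction for Molecular Cell Illustration
Version: 0.1.0
Authors@R:
    person("Mesopaint", "Developers", email = "mesopaint@example.org", role = c("aut", "cre"))
Description: A scriptable, GUI-free engine for building 2.5D illustrations of
    the molecular interior of cells and viruses. Molecular "ingredients"
    (soluble proteins, membrane-bound proteins, fiber subunits) are built from
    atomic structures or transparent sprite images, given automatically
    inferred 2D colliders via covariance eigen-decomposition of the image
    contour, and painted onto a three-layer canvas governed by a deterministic
    position-based rigid-body solver. Articulated fiber and membrane chains,
    membrane-protein rail constraints, grouping, locking with convex-hull
    collider simplification, distance measurement, CellPACK-style recipe
    serialization, scene files, zip bundles, and raster rendering are all
    exposed as plain R functions and a scripted command-line session runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    zip
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
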