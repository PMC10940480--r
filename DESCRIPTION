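Package: fiberperm
Title: Microstructure and Permeability of Hollow-Fiber Oxygenator Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for relating the microstructure of hollow-fiber
    membrane oxygenator bundles to their hydraulic permeability. Builds periodic
    repetitive units of orthogonal and angled fiber layups from geometric
    parameters (fiber diameter, wall thickness, pitch, layer angle), applies
    press-fit compression models (rigid interpenetrated fibers or an
    area-preserving flattened-contact approximation), voxelizes the fluid
    domain with a minimum-gap rule at fiber contacts, solves steady
    incompressible creeping flow on the voxel lattice with periodic and
    symmetry boundary conditions, and extracts directional Darcy permeability
    and its variation with press-fit degree. Includes closed-form fixtures
    (plane channel, square arrays of parallel cylinders) for solver
    verification, and a calibrated Neo-Hookean material model of the fiber
    wall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
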