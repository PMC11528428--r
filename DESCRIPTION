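Package: smlmeq
Title: Equilibrium Constants for Protein Interactions from
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates protein-protein association (Ka) and dissociation
    (Kd) equilibrium constants in situ from single-molecule localization
    microscopy (SMLM) data.  Provides qPAINT molecular counting from
    DNA-PAINT blinking kinetics, three estimators of the membrane area
    accessible to the interacting molecules (Delaunay tessellation,
    Voronoi tessellation and a thresholded kernel surface density,
    ks-density), proximity-criterion pair counting against complete
    spatial randomness (CSR) references, equilibrium-constant estimation
    on surface (um^2) and molar scales with extrapolation to infinite
    dilution, stepwise cluster association constants, Langmuir-type
    cluster occupancy analysis, and a seeded simulation engine that
    places two interacting species at equilibrium inside cell-shaped
    regions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    igraph,
    interp,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deldir,
    jsonlite,
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
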