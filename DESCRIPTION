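Package: helixvol
Title: Mitochondrial Helix Volume and Phylogenetic Morphometrics of
    Passerine Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the volume of the mitochondrial helix of passerine
    spermatozoa from scanning-electron-microscopy width and position
    measurements, treating the helix cross-section as an ellipse wound
    around a tapering flagellum, and runs the accompanying phylogenetic
    comparative analyses: midpiece-flagellum allometry, flagellum and
    helix tapering along the cell, gyre-interval scaling, volume versus
    midpiece length, and nucleus-flagellum diameter correlation.
    Phylogenetic generalized least squares with Pagel's lambda and a
    phylogenetic linear mixed model with REML variance components are
    implemented directly; a synthetic-data module generates 3D helical
    cells with numerically integrated true volumes and simulated trait
    evolution on Yule trees so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    MASS,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
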