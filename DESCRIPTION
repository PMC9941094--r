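Package: espvisc
Title: Antibody Viscosity Prediction from Voxelized Surface Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts high-concentration antibody solution viscosity from the
    electrostatic potential on a thin shell outside the molecular surface of
    the Fv domain. Provides a grid-based solvent-excluded surface, a
    finite-difference linearized Poisson-Boltzmann solver, masked voxel input
    grids (electrostatic and Eisenberg hydrophobicity channels), a small 3D
    convolutional network trained with rotation augmentation and
    cross-validation ensembling, integrated-gradients attribution with
    surface-patch analysis, sequence- and structure-based baseline models,
    evaluation metrics with bootstrap confidence intervals, and a synthetic
    structure generator so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
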