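Package: hydroniche
Title: Quantification of 3D Hydrogel Bone-Marrow-Mimic Leukemia Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo 3D hydrogel tri-cultures of
    acute lymphoblastic leukemia (ALL) cells with mesenchymal stromal and
    endothelial cells: 3D segmentation of confocal z-stacks and morphometry
    of vasculature-like networks, single-cell proximity and migration-depth
    statistics, timelapse track linking and motility kinetics, dye-dilution
    proliferation classification, and bead-normalized 2D-versus-3D drug
    response scoring.  Includes an agent-based synthetic tri-culture
    generator and voxel renderer so every stage is testable without
    microscopy or cytometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
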