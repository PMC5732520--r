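Package: femstrength
Title: CT-Based Finite Element Prediction of Proximal Femur Fracture Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specimen-specific finite element pipeline for predicting the
    fracture load and stiffness of the proximal femur from calibrated
    quantitative CT. Covers phantom-based HU-to-density calibration,
    surface extraction and the stance-configuration specimen cut,
    tetrahedral meshing with a cortical shell overlay, density-based
    material mapping through power-law modulus/yield relations with a
    Drucker-Prager yield surface, a displacement-controlled nonlinear
    finite element solver, extraction of fracture load and stiffness from
    force-displacement curves, cohort-level validation statistics, and a
    synthetic-specimen generator that emulates calibrated CT phantoms and
    mechanical test recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
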