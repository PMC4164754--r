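Package: elastofem
Title: Regularization-Free Young's Modulus Reconstruction for Quasi-Static
    Ultrasound Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element direct inversion of relative Young's modulus from
    quasi-static ultrasound elastography displacement fields. A bicubic
    B-spline free-form deformation model smooths speckle-tracked axial
    displacements and derives the lateral field from plane-strain
    incompressibility; the inversion uses a unit-modulus boundary ring
    instead of force or displacement boundary data and needs no
    regularization. Includes a synthetic simulation stack (plane-strain FEM
    forward solver, inclusion phantoms, convolution point-spread-function RF
    synthesis, normalized cross-correlation speckle tracking) and evaluation
    metrics for reconstruction accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    broom,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
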