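Package: fibrelast
Title: Fiber-Based Hyperelastic Constitutive Modelling of Uniaxial Tensile Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and comparing incompressible hyperelastic
    constitutive models (Neo-Hookean, Yeoh, Ogden, Gasser-Ogden-Holzapfel, and a
    transversely isotropic fiber-matrix model) against uniaxial tensile
    stress-strain curves of soft biological tissue. Provides uniaxial
    kinematics (principal stretches, first and fourth invariants), analytic
    nominal-stress functions with a finite-difference oracle, a two-stage
    calibration protocol (matrix constants on circumferential data, fiber
    constants on longitudinal data), percent-RMSE model comparison, and a
    synthetic tensile-curve generator emulating anisotropic urethral tissue
    so the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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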