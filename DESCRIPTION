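Package: hopsim
Title: Tracking Simulations of Body-Weight-Supported Hopping on a Planar
    Musculoskeletal Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-tracking direct-collocation simulations of single-leg
    hopping under body-weight support (emulated hypogravity) on a reduced
    planar musculoskeletal model. Provides Hill-type muscle-tendon dynamics
    with calibrated tendon compliance, twice continuously differentiable
    Hunt-Crossley foot-ground contact, polynomial muscle geometry, trial
    preprocessing (cropping, Butterworth filtering, spline resampling,
    inverse dynamics), a Legendre-Gauss-Radau collocation transcription of
    the tracking optimal control problem with an augmented-Lagrangian
    solver, joint reaction force analysis, a synthetic hopping-trial
    generator for five gravity conditions, and a muscle cross-sectional
    area adaptation model that converts quadriceps force profiles into
    hypothetical training volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    deSolve,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
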