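Package: yeastcolony
Title: Multiscale Modelling of Yeast Colony Growth and Metabolic Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for data-driven multiscale modelling of budding yeast
    colonies. Implements a three-state (glucose, ethanol, quiescent)
    metabolic growth model of the diauxic shift, Bayesian calibration and
    hypothesis testing for the metabolic switching routes via
    population-based MCMC and thermodynamic integration, a coarse-grained
    3D lattice simulator of colony growth with thresholded cell-mass
    movement and nutrient transfer on agar, and Gaussian-process Bayesian
    optimization of the spatial nutrient transfer rates against colony
    footprint-area time series. Includes synthetic data generators for
    growth curves, population-composition observations and footprint
    areas, so the full pipeline can be exercised without experimental
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
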