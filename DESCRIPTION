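Package: lungflow
Title: Optimal Respiratory Airflow Patterns for Multicompartment Lung Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models mechanical ventilation of a heterogeneous lung as a
    2^n-compartment dichotomous airway tree with volume-dependent (piecewise
    linear, sigmoidally smoothed) compliance, and computes optimal inspiratory
    and expiratory airflow patterns by calculus of variations. The inspiratory
    optimum minimizing volume acceleration plus work of breathing has a
    matrix-exponential closed form; the expiratory optimum minimizing volume
    acceleration plus integral squared driving pressure solves a nonlinear
    fourth-order two-point boundary-value problem by Lobatto IIIA collocation.
    Includes forward simulation under arbitrary pressure waveforms,
    driving-pressure reconstruction, performance-functional evaluation,
    breathing-cycle orchestration with limit-cycle analysis, and an
    independent direct-transcription optimizer for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
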