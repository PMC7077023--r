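Package: csfclear
Title: Reduced-Order Modelling of Cerebrospinal Fluid Tracer Clearance
    Under Filtration and Drainage Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale analysis of solute clearance from the
    cerebrospinal fluid (CSF) after subarachnoid haemorrhage. Provides a
    synthetic subject-like neuroaxis generator (axial area, perimeter and
    hydraulic-diameter profiles with compartment volume bookkeeping), a
    cardiac-driven CSF pulsation waveform, axial hydrodynamic
    characterisation (Reynolds and Womersley numbers, peak mean
    velocities), a shear-augmented dispersion similitude table
    (Schmidt, oscillatory Peclet, Womersley-squared, maximum enhancement,
    effective diffusivity, Sherwood numbers), steady-streaming
    quantification from periodic velocity fields, a one-dimensional
    finite-volume frozen-flow-field tracer transport solver comparing
    dual-lumen filtration (Neurapheresis) therapy against lumbar drain, a
    synthetic fluorescence time-lapse imaging emulator with
    intensity-to-concentration quantification, and Bland-Altman /
    regression agreement statistics between spatio-temporal
    concentration maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
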