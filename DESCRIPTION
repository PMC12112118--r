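Package: ohkin
Title: Hydroxyl-Radical-Driven Kinetics of Electrochemical Pollutant Oxidation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semiempirical kinetic modelling of pollutant fate during
    electrochemical advanced oxidation. Infers the transient hydroxyl-radical
    concentration profile from easily measured hydrogen peroxide via a
    recombination-equilibrium proportionality, drives a lumped sequential
    reaction chain (parent pollutant, lumped aromatic intermediates, CO2) with
    that profile, estimates second-order rate constants by bounded nonlinear
    least squares with confidence intervals, generalizes the radical yield
    linearly across applied current densities, and predicts the time-dependent
    toxic-unit mixture toxicity of the treated solution from per-compound LC50
    data. Includes an exact closed-form (Bateman) solution of the chain in the
    radical-exposure variable used as an independent oracle, a synthetic
    measurement generator for estimator validation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
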