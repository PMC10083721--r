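Package: erleak
Title: Kinetics of Thapsigargin-Induced ER Calcium Leak and Cytosolic
    Calcium Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of thapsigargin-induced Ca2+
    mobilisation in live-cell imaging data. Converts ratiometric sensor
    readings (FURA-2, D1ER) to concentrations, extracts model-free
    transient metrics (baseline, peak amplitude, AUC, duration), detects
    the depletion inflection point from smoothed derivatives, estimates
    first-order clearance and ER depletion rates, and fits the Bateman
    one-compartment model of cytosolic Ca2+ transients driven by the ER
    Ca2+ leak. Includes closed-form model analytics, amplification /
    attenuation phase-diagram simulations, and a seeded synthetic-data
    generator emulating paired cytosolic/ER traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
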