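Package: thermogate
Title: Thermodynamic Gating Analysis for Voltage- and Heat-Activated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium thermodynamic modelling and measurement pipeline for
    the temperature sensitivity of voltage-gated ion channels. Implements a
    four-state allosteric gating scheme coupling a voltage-sensor transition
    to a heat-sensitive pore-opening transition, single-Boltzmann
    conductance-voltage fitting, temperature-coefficient (Q10) measurement
    with activation-threshold detection, Van't Hoff enthalpy/entropy
    estimation, closed-state-inactivation availability analysis, and a
    synthetic inside-out patch-clamp sweep generator (voltage steps, ramps,
    slow temperature ramps, leak, conductance temperature dependence, noise)
    so the whole pipeline is testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
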