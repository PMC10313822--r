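Package: bilayertools
Title: Single-Channel Planar Bilayer Electrophysiology and Binding Analysis
Version: 0.1.0
Authors@R: person("Channel", "Biophysics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-channel recordings from planar lipid
    bilayers and surface plasmon resonance (SPR) binding assays of anion
    channels. Provides closed-form electrodiffusion calculations (Nernst
    potentials, Goldman-Hodgkin-Katz reversal potentials, permeability-ratio
    inversion), seeded simulators for two-state Markov gating, dose-response
    tables and 1:1 Langmuir sensorgrams, half-amplitude trace idealization
    with open-probability and dwell-time statistics, and parameter-estimation
    routines for current-voltage lines, Hill IC50 inhibition curves, and
    steady-state or kinetic Langmuir binding models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
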