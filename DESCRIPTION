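Package: rhinoflow
Title: Nasal Resistance Measurement from Pressure-Flow Recordings
Version: 0.1.0
Authors@R:
    person("rhinoflow", "developers", email = "rhinoflow@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for two-channel rhinomanometry recordings
    (transnasal pressure in Pa, nasal airflow in cm3/s, sampled at 100 Hz):
    streaming segmentation of respiratory cycles, automatic rejection of
    artifact cycles by combined FFT dominant-frequency and peak-to-peak
    amplitude thresholds, natural cubic spline resampling of accepted cycles
    to a fixed 2000-point grid, and computation of four nasal-resistance
    indicators (classic mean resistance at the 150 Pa reference pressure,
    vertex resistance, effective (RMS) resistance, and Broms resistance by a
    polar-coordinate least-squares fit). Includes a seeded synthetic breath
    simulator emulating common interference scenarios, an exhaustive
    threshold grid search, within-group stability analysis, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
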