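Package: memskin
Title: Memristive Voltage-Current Loop Analysis for Human Skin Bioimpedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of non-linear ("memristive") electrical
    measurements on human skin. Provides a biophysical circuit simulator
    (sweat-duct memristor in parallel with a stratum-corneum thermistor and
    capacitance), generators for the standard low-frequency voltage stimulus
    grid, per-loop statistics of pinched hysteresis V-I curves (non-linearity
    parameter, lobe area, maximum current, pinched-point detection, phase
    shift, lock-in admittance), and cohort-level aggregation including
    noise-exclusion filters, grouped summaries, a random-intercept mixed
    model and the linear/non-linear measurement-range boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
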