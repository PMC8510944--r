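Package: blasttube
Title: Shock-Tube Gas Dynamics, Axisymmetric Blast-Wave Simulation, and
    Blast-Injury Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing confined-space blast-tube experiments on
    body-armor efficacy. Implements ideal shock-tube theory (normal-shock jump
    relations and the diaphragm-pressure-ratio to shock-Mach-number closure),
    exact and HLLC Riemann solvers for the 1D Euler equations, a finite-volume
    weighted-average-flux (WAF) compressible-flow solver in 1D and axisymmetric
    2D with solid-body masking, blast waveform metrics (arrival time, peak
    overpressure, positive-phase duration and impulse, Friedlander model fits),
    and the injury-outcome statistics used on small animal cohorts (exact
    Fisher tests, split-plot repeated-measures ANOVA, two-group t-tests),
    together with synthetic-data generators for cohorts, physiological time
    series and pressure traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    minpack.lm,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
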