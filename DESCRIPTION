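Package: saccpop
Title: Population Decoding of Interceptive Saccade End-Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for population decoding of
    saccade end-positions from peri-saccadic spiking activity. Generates
    synthetic cohorts of spatially tuned neurons recorded during regular
    (stationary-target) and interceptive (moving-target) saccades, detects
    saccades from 1 kHz eye traces with a double velocity criterion, builds
    interpolated spatio-temporal tuning fields, resamples Poisson
    pseudo-populations, trains a shallow feed-forward network to decode
    saccade end-position, and computes the associated behavioral and
    decoding statistics (intercept regression, endpoint ellipses,
    similarity index, confusion matrices, center bias, error fields, and
    sliding-window time courses).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
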