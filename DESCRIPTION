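Package: beemill
Title: Tethered Flight-Mill Telemetry Processing and Dose-Effect Analysis for Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tethered flight-mill assays of insect flight
    performance. Reads per-revolution ("circuit") interval logs and subject
    metadata, detects flight stoppages from inter-event intervals, applies
    protocol-based circuit cleaning, and computes endurance and velocity
    metrics per flight session. Implements a reproducible cohort filter
    cascade with body-size trimming, fits the associated suite of
    (generalised) linear mixed models with a random-intercept fallback, and
    models binned velocity trajectories over the early flight phase. Includes
    a calibrated synthetic-cohort simulator so the complete pipeline can be
    exercised and power-checked without hardware data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
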