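Package: fitnessfatigue
Title: Fitness-Fatigue Systems Models for Resistance-Training Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Impulse-response (Banister-type) systems models relating daily
    training doses to performance, fitted jointly to a cohort with shared
    time constants and subject-specific gains by pooled nonlinear least
    squares (variable projection with multistart). Includes training-load
    quantification for ladder-climbing resistance exercise in rats,
    degrees-of-freedom accounting and nested F-ratio model comparison,
    single-bout response characteristics and positive/negative influence
    decomposition, and a seeded synthetic-cohort generator emulating a
    progressive-load climbing protocol for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
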