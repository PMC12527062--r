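Package: insolestride
Title: Model-Based Stride Length and Walking Distance Estimation from
    Smart Insole Signals
Version: 0.1.0
Authors@R:
    person("Insole", "Gait Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates average stride length and total walking distance
    (e.g. over a six-minute walk test) from foot-worn smart-insole
    recordings that combine antero-posterior acceleration with plantar
    pressure channels. Gait cycles are segmented from great-toe pressure
    (toe-off) and antero-posterior acceleration maxima (heel-strike);
    stride length is estimated against a boundary-constrained cubic
    reference gait model either by the ratio of swing-phase acceleration
    director coefficients or by dynamic-time-warping scaling. Includes a
    synthetic gait-signal generator with ground truth, validation
    statistics (accuracy, median/interquartile, exact Mann-Whitney U,
    intraclass correlation with confidence intervals), bundled
    per-participant reference tables, and a command-line interface.
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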