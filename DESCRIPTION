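Package: rowzone
Title: Heart-Rate Zone Analysis of On-Water Rowing Training Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 1 Hz on-water rowing streams (stroke rate,
    boat velocity, heart rate). Derives individualised five-zone heart-rate
    training models from incremental ergometer step tests (cubic lactate-curve
    fit, first-rise LT1, modified D-max LT2), applies a reproducible filter
    cascade to raw session streams (stroke-rate and velocity bands, 15 s
    velocity smoothing, prognostic-velocity conversion, zone classification,
    gradient and minimum-run artifact filters), and reproduces the standard
    statistical surfaces: per-zone summaries, kernel-density overlapping
    index between zones, linear mixed-effects zone contrasts with false
    discovery rate post-hocs, stroke-rate bin summaries, and correlation /
    progression analyses. A synthetic-data module simulates step tests and
    multi-segment sessions with known ground truth (stroke-rate to velocity
    power law, first-order heart-rate lag, drill and race-start artifacts)
    so the whole pipeline is testable without athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    lmerTest,
    emmeans,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
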