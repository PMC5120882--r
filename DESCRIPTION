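Package: perisacc
Title: Peri-Saccadic Detection Performance and Recovery-Time Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for psychophysical detection performance around
    visually guided saccades: velocity-threshold saccade detection from 1000 Hz
    eye-position traces, trial classification and inclusion rules, time-binned
    hit rates with Wilson score confidence bands, and a recovery-time estimator
    based on sequential one-sided Boschloo exact unconditional tests against a
    pooled post-saccadic baseline. Includes a synthetic-data generator that
    emulates the timing and geometry of peri-saccadic attention experiments
    (trial schedules, saccade kinematics with configurable latency mixtures,
    and a piecewise performance time-course with suppression and step
    recovery), so the whole chain can be exercised and calibrated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
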