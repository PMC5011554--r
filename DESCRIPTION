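Package: ergotherm
Title: Objective Exercise-Fatigue Monitoring from Training-Device Thermometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective monitoring of exercise-induced fatigue from
    minute-sampled temperature telemetry of a leg-training device recorded
    together with heart rate. Implements a first-order thermal model linking
    leg work output to the device temperature rise in high- and
    low-sensitivity modes, a seeded synthetic-cohort generator with
    intensity-dependent fatigue and a diurnal fatigability effect, phase
    segmentation and joint work-output/heart-rate fatigue-onset detection,
    personalized exercise-dose calibration and threshold-notification
    tracking, and split-half fatigability statistics with afternoon/evening
    group comparisons and compliance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
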