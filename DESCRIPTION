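Package: smokesense
Title: Detection of Cigarette Smoking Arm Movements from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cigarette smoking events from body-worn tri-axial
    accelerometer and gyroscope recordings. Implements two puff-level
    detectors -- an edge-detection method operating on denoised,
    gravity-free acceleration, and a sliding-window support-vector-machine
    classifier over statistical window features -- together with the
    grouping rule that aggregates consecutive hand-to-mouth puff movements
    into whole-cigarette events, ROC-based configuration selection, and a
    seeded synthetic-session generator that emulates laboratory smoking
    topography (puff counts, inter-puff intervals, cigarette durations) so
    the full pipeline can be exercised and validated without recorded
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
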