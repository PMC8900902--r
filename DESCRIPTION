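Package: emawear
Title: Compliance and Detection Validity for Sensor-Triggered Ecological
    Momentary Assessment in Family Deployments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in-home family deployments that pair
    wrist-worn eating-gesture sensing with ecological momentary assessment
    (EMA). Implements temporal clustering of hand-to-mouth gestures into
    detected eating events, hourly time-triggered and event-triggered EMA
    prompt scheduling with delivery and answer-state bookkeeping, the
    participation-interval algorithm that fuses answered prompts with
    accelerometer and proximity-beacon availability, compliance rates and
    logistic models of their predictors, and precision-based validity
    analysis of in-field detections. A synthetic deployment generator with
    known ground truth drives the whole pipeline, enabling
    parameter-recovery and property testing without access to raw field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    hms,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
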