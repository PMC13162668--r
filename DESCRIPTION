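Package: penwatch
Title: Zone-Occupancy Behavior Inference and Thermal Comfort for Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-frame object-detector bounding boxes from pen cameras
    into ethogram time budgets (lying, standing, eating, drinking) for
    group-housed pigs, using feeder/drinker zone occupancy and feeding-window
    gating. Computes microclimate thermal-comfort indices (dew point, black
    globe humidity index) with physiological heat-stress classification, and
    evaluates detections against ground truth (precision, recall, average
    precision, duration agreement). Includes a synthetic barn simulator that
    emulates the cameras and the trained detector: diurnal microclimate,
    Markov behavior dynamics, and configurable detector noise with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
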