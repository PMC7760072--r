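Package: stalltrack
Title: Quality Control and Behaviour Analytics for Keypoint Tracks of Stabled Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing, validation and behaviour analytics for
    keypoint trajectories of horses filmed in box stalls with time-lapse
    cameras. Detects teleport mislabels with a squared-displacement jump
    statistic and a 200-pixel rule, screens for long missing-prediction
    runs, scores detections against ground-truth annotations
    (sensitivity, error rate, accuracy over first/last-1000-image
    windows), compares model versions with paired t-tests and one-way
    ANOVA, and derives occupancy heat maps, time-in-region and behaviour
    time budgets, a rolling-variance weight-shifting signature, and a
    rule-based four-class ethogram classifier. A seeded synthetic stall
    simulator (Markov behaviour states, three body markers, occlusion,
    dropouts and teleport artifacts) makes every stage testable without
    video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
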