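Package: gazevents
Title: Classification of Natural-Viewing Gaze Events from Mobile Eye-Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies gaze recordings from head-mounted (mobile) eye
    trackers into four natural-viewing gaze events (gaze fixation, gaze
    pursuit, gaze shift, gaze following) using only the eye-movement signal
    and the scene-camera video. Extracts per-sample eye-movement velocity
    and direction, head-rotation velocity and direction and a body
    translation proxy from classical monocular visual odometry, and a
    zero-normalized cross-correlation similarity score between consecutive
    gaze-centered image patches; aligns all channels by cubic interpolation
    and feeds them to a seeded random-forest classifier. Includes
    event-preserving sample extraction for balancing and splitting,
    sample-level and event-level (majority-voting) precision/recall/F1
    evaluation with leave-one-out and train-test-split procedures, and a
    seeded synthetic natural-viewing recording simulator so the complete
    pipeline can be exercised without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
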