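Package: courtTrack
Title: Multi-Cue Player and Ball Tracking in Court-Sport Video
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tracking of the four players and the ball in fixed-camera
    court-sport video (e.g. beach volleyball). Implements planar homography
    court calibration, an adaptive Gaussian-mixture background model with
    foreground and movement masks, HSV histogram appearance scoring with
    Bhattacharyya distances over stacked subwindows, a classical multi-cue
    particle filter and a rigid-grid integral-histogram tracker for the
    players, connected-component ball candidate detection with an isolation
    test, two ballistic trajectory estimators (incremental trajectory growth
    and Hough-line grouping), ball-contact time-point estimation from
    parabola intersections, an evaluation protocol against reference
    annotations, and a seeded synthetic-scene generator with exact ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
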