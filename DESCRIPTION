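Package: squatscore
Title: Rule-Based Scoring of Body-Weight Squat Sets from 2-D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates body-weight squat exercise sets recorded as 2-D pose
    keypoint time series (17-part PoseNet/COCO layout). Derives shoulder and
    knee widths, the knee/shoulder ratio, and normalized hip height; segments
    a set into fixed-cadence 6-second repetition rounds; scores each round on
    knee width, hip depth, and rhythm against an optimal cosine cadence; and
    maps round scores to the background-music/noise volume envelope used for
    audio feedback. Includes a seeded synthetic squat-kinematics simulator so
    the whole pipeline is testable without video, plus survey-cohort grouping
    and descriptive summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
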