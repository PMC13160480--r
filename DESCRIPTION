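Package: uprom
Title: Markerless Upper-Limb Range of Motion from 2D Pose Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes shoulder and elbow joint angles from 2D pose-landmark
    time series (33-point whole-body topology) using the interior-angle
    vector formula, extracts per-repetition functional range of motion for
    clinical upper-limb tasks, and provides the method-comparison and
    reliability statistics used to validate markerless motion-capture tools
    against digital goniometry: Bland-Altman limits of agreement with
    proportional-bias testing, ICC(2,1) two-way random-effects absolute
    agreement with McGraw-Wong confidence intervals, standard error of
    measurement, and minimum detectable change. Includes forward-kinematic
    simulators of task trajectories and paired-rater data with known ground
    truth, and a command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
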