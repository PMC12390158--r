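Package: spinewear
Title: Lumbar Spine Posture Analysis from Trunk-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Spinewear", "Maintainers", email = "maintainers@spinewear.dev",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating lumbar spine posture and
    movement from paired trunk-worn inertial measurement units (IMUs) recorded
    in the laboratory and in daily life. Covers inter-sensor clock
    synchronization by cross-correlation with linear drift correction,
    stillness-based gyroscope bias estimation and removal, gradient-descent
    (Madgwick-type) orientation fusion, lumbar joint Euler angles from paired
    spine sensors, hop-burst task segmentation, data-quality exclusion for
    magnetic disturbance, seated transport and non-physiological angles, five
    reference-posture normalization strategies, and repeatability analysis via
    the two-way random-effects absolute-agreement average-measures intraclass
    correlation coefficient ICC(A,k). A synthetic-cohort generator produces
    ground-truth raw sensor streams with known clock skew, gyro bias, mounting
    offsets and magnetic disturbances so that every stage is verifiable
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
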