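Package: poseagree
Title: Agreement Analysis for 2D Human Pose Keypoint Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Validates a candidate stream of 2D human-pose keypoints against
    a reference stream. Reads OpenPose Body25-style JSON, Panoptic-style
    15-landmark pose JSON, and generic long-format CSV; computes interior
    joint angles from keypoint triplets; smooths the angle series with a
    Bartlett (triangular) window, imputes missing values with a centered
    moving average, and frame-aligns candidate and reference; and reports a
    full method-comparison panel per joint: bias with 95% confidence
    interval, MAE, MAD, RMSE, sMAPE, intraclass correlation ICC(A,2) with
    F-based confidence intervals and Fleiss classification, per-video ICC,
    box-plot summaries, augmented Dickey-Fuller stationarity checks, and
    cross-correlation temporal-lag diagnosis. Ships a synthetic
    paired-skeleton generator with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
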