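Package: rowtrack
Title: Multiple Object Tracking and Re-Identification for Row Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tracking-by-detection toolkit for plants growing in parallel
    crop rows, imaged by a camera translating along the row (for example on
    a field robot). Fits the crop center line, splits detections into lanes,
    builds a neighbor-based geometric identity feature for each plant, and
    associates detections across frames with a fused feature-distance /
    Kalman-IOU cost matrix solved by the Hungarian algorithm. A persistent
    object library indexed by in-lane planting order re-identifies plants
    that leave the field of view and re-enter, including under reversing
    motion. Includes a synthetic field simulator that emulates the
    acquisition geometry (lanes, spacing, forward/stop/reverse camera
    motion, detection noise), MOTChallenge text-file input/output, and MOT
    evaluation metrics (IDF1/IDR/IDP, ID switches, HOTA and its
    components).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
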