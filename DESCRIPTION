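Package: rotoloc
Title: Real-Time Ultrasound Guidance for Breast Tumor Rotational Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and validating an intraoperative
    ultrasound guidance pipeline for vacuum-assisted rotational resection of
    breast tumors. Implements the geometric cutter-slot activation decision
    rules for the two surgical workflows (co-visible and alternating-view),
    declarative layer plans with exact parameter and FLOP accounting for the
    lightweight detection architectures used for cutter-slot and tumor
    localization, detection evaluation metrics (precision, recall, mAP50,
    specificity, Matthews correlation, error rate) with patient-level fold
    splitting, a synthetic ultrasound session generator with scripted
    ground truth, and a frame-stream pipeline with annotation, keyframe
    extraction and prompt emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
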