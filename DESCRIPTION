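Package: lineagetracer
Title: Semi-Local Neighborhood Cell Lineage Tracing for 4D Nuclear Detections
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cell lineage trees from per-frame 3-D nuclear
    detections produced by time-lapse fluorescence microscopy.  Tracking is
    layered: a conservative mutual nearest-neighbor pass links unambiguous
    1-to-1 correspondences; local increases in cell count are forced into
    tentative track bifurcations whose semi-local neighborhoods are
    classified by Naive Bayes into division, two-cell movement/false
    negative, detection false positive, or other; each class triggers a
    specific repair action (accept division, rewire and interpolate gaps,
    delete spurious tracks, or reassign).  Ships a synthetic dividing-embryo
    simulator with ground truth and detection-error injection, plus lineage
    evaluation metrics (instantaneous and cumulative accuracy, division
    PPV/sensitivity, density-stratified error counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
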