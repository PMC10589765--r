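Package: wormsynth
Title: Synthetic C. elegans Detection Datasets, Self-Labeling and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic plate-microscopy scenes of C. elegans with
    automatically derived YOLO-format bounding-box labels, from parametric worm
    body masks (including dumpy-like and long-like strain morphologies) rendered
    with a procedural appearance model onto synthetic agar backgrounds.
    Provides the standard object-detection augmentation repertoire (HSV jitter,
    translate/scale/flip, 2x2 mosaic, letterbox resize), a classical CPU
    baseline detector, a count-filtered supervised self-labeling curation
    workflow, detection evaluation metrics (precision, recall, AP at IoU 0.5),
    and a small-sample replicate-statistics harness (exact n = 3 Shapiro-Wilk
    and paired Student's t-tests) for comparing detector training methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
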