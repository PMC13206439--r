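Package: noduleCurriculum
Title: Hybrid Curriculum Construction for Lung Nodule Detection on CT Slices
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detector-agnostic toolkit for difficulty-aware (curriculum)
    training of lung nodule detectors on 2D chest CT slices. Scores per-slice
    detection difficulty from handcrafted image and annotation factors
    (nodule count, size, shape irregularity, image quality) and from teacher
    detector prediction summaries (confidence, count discrepancy, prediction
    density), fuses the two sources with a convex mixing coefficient,
    partitions slices into simple/medium/complex tiers and emits a
    three-stage progressive training curriculum together with a
    no-curriculum baseline configuration. Also provides the surrounding
    pipeline: slice quality assessment, CLAHE contrast enhancement,
    aspect-preserving pad-and-resize, sub-3 mm nodule filtering,
    nodule-oriented slice sampling, patient-level splitting and subsampling
    protocols, a from-scratch mAP50/mAP50-95 evaluator, YOLO-format label
    I/O, and a synthetic CT-like fixture generator with controllable
    difficulty structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, Classification, Preprocessing, Visualization
RoxygenNote: 7.3.3
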