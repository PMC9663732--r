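Package: bmdetect
Title: Lesion-Level Detection of Brain Metastases on Black-Blood MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Framework for lesion-level evaluation of slice-wise bounding-box
    detection of enhancing brain metastases on contrast-enhanced
    black-blood-like 3D MRI. Provides a seeded phantom generator (spherical
    hyperintense lesions plus partially suppressed vessel-like false-positive
    sources), threshold-and-morphology brain extraction with per-slice 0-1
    intensity normalization, a deterministic reference per-slice detector
    behind a pluggable interface, adjacent-slice IoU linking of 2D boxes into
    numbered 3D lesions with a multi-slice filter, lesion-level matching with
    a one-slice true-positive rule, the sensitivity/precision/F1/false
    positives-per-scan metric suite, and a five-fold cross-validation harness
    with table-style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
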