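Package: wbcdetect
Title: Two-Stage Detection and Counting of White Blood Cells in Bone Marrow
    Smear Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and counts white blood cells in stained bone
    marrow smear microscopy images with a two-stage detector: a residual
    convolutional backbone feeding an augmented feature pyramid (top-down plus
    bottom-up fusion pathway), an anchor-based region proposal network, a
    soft-attention bounding-box localizer refined by an actor-critic agent,
    and an RoIAlign classification head with multi-class non-maximum
    suppression. Includes a seeded synthetic smear-image generator with COCO
    ground truth, VIA-to-COCO annotation conversion, augmentation utilities,
    COCO-protocol AP/AR evaluation, per-class cell counting, and a command
    line interface. All network layers and their gradients are implemented in
    plain R on BLAS matrix operations, so training and inference run on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
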