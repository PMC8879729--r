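Package: lordometry
Title: Geometric Morphometry of the Lumbar Spine from Vertebra Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for grading lumbar lordosis from localized and segmented
    lumbar vertebrae in mid-sagittal images. Reads YOLO-format vertebra
    detections and per-slice instance label images, detects the four
    endplate corners of each vertebral body with a Harris corner detector
    on Gaussian-smoothed masks, computes the lumbar lordotic angle (LLA,
    L1 superior endplate versus sacral superior endplate) and the
    lumbosacral angle (LSA, L5 inferior endplate versus sacral superior
    endplate), and grades lordosis as hypolordotic, normal or
    hyperlordotic. An alternative grading route measures the pixel area of
    the closed polygon through the six vertebra centroids. Detection and
    angle quality metrics (centroid Euclidean error, intersection over
    union, mean absolute angle error, precision/recall, average precision)
    and a parameterized synthetic spine-phantom generator with known
    ground-truth geometry are included, so the whole pipeline is testable
    end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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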