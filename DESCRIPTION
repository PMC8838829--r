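Package: filletbend
Title: Sideview Imaging Analysis of Fillet Bending for Wooden Breast Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect the wooden breast condition in broiler breast
    fillets from sideview image sequences of a conveyor discharge edge.
    Implements software trigger-line motion sensing, a five-stage
    morphological segmentation pipeline, two bending descriptors (a
    scale-invariant bending energy computed from a medial-axis skeleton
    fitted with a quadratic curve, and a normalized minimum centroid-to-axle
    distance), per-fillet feature extraction, group statistics (one-way
    ANOVA with Tukey letters, Spearman rank correlation), and binary
    classification with repeated stratified cross-validation scored by
    overall accuracy, balanced accuracy, F1 and the Matthews correlation
    coefficient. A synthetic conveyor-scene simulator with exact ground
    truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    MASS,
    class,
    e1071,
    png,
    rpart,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
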