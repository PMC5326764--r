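Package: spikesight
Title: Bag-of-Visual-Words Growth-Stage Categorization for Wheat Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-categorization pipeline for detecting wheat growth
    stages (ear emergence, flowering) in proximal RGB canopy imagery.
    Implements decorrelation-stretch color enhancement, SIFT scale-space
    keypoint detection and description, a K-means visual vocabulary,
    locality-constrained linear coding (LLC), spatial-pyramid pooling, and
    a linear support vector machine with the explicit Hellinger feature
    map, plus a seeded synthetic-fixture generator, an ablation harness
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
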