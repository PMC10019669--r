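Package: histomorph
Title: Pathomic Feature Extraction and Tile Classification for H&E Prostate Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of hematoxylin-and-eosin stained
    prostate histology. Whole-slide images are divided into coordinate-indexed
    tiles, matched against pathologist annotation masks under a majority-coverage
    rule, and segmented into stroma, epithelium and lumen by stain color
    deconvolution. Glands are reconstructed from lumen components and their
    epithelial walls, and eight morphometric features (whole-tile stromal and
    epithelial area fractions; per-gland epithelial area, roundness and wall
    thickness, luminal area and roundness, and cell fraction) are summarized per
    tile as mean, median and variance. A bagged decision-tree ensemble classifies
    tiles at three levels of grading specificity (all Gleason patterns,
    high- vs low-grade vs benign, cancer vs non-cancer), with confusion-matrix
    evaluation and slide-level prediction maps. A seeded synthetic histology
    generator with per-gland ground truth supports testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
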