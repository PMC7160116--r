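Package: mitoscan
Title: Rule-Based Image Analysis and Hit Calling for High-Content Mitotic
    Phenotype Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-division phenotypes from multi-channel
    fluorescence screening images and turns them into ranked hit lists.
    Provides a synthetic 384-well screen simulator with full per-cell ground
    truth; nucleus/cytoplasm segmentation and spot detection; a rule cascade
    classifying dead cells, mitotic figures, anaphase/telophase pairs,
    chromosome segregation errors, multinucleated cells and cytokinetic
    bridges; plate normalization with Z-score hit calling and replicate
    concordance; z-stack intensity-ratio and inter-kinetochore distance
    measurements; and combination statistics for loss-of-function genomics
    (intersection-union tests, Simes window clustering, Benjamini-Hochberg
    and empirical FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
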