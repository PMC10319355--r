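Package: wormpheno
Title: Image-Based Morphometry and Behavioral Phenotyping for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipelines for phenotyping adult Caenorhabditis
    elegans: body morphometry (tip-to-tip length, middle width, and total
    volume by a 30-segment frustum-of-cone sum) from calibrated grayscale
    micrographs via segmentation, skeletonization and sub-pixel midline
    extraction; intestinal luminal width from perpendicular transects in
    the posterior gut; defecation motor-program rhythm statistics (cycle
    length, aBoc and expulsion frequencies) from BORIS-style behavioral
    event logs; and cAMP-reporter bioluminescence plate normalization
    (dual-read collapsing, fold change over the ligand-free control,
    assay-level aggregation, basal receptor activity). Includes synthetic
    generators for worm images, event logs and plates with analytically
    known ground truth, so every stage is validated against closed-form
    and quadrature oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
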