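Package: tundramorph
Title: Object-Based Mapping of Polygonal Tundra Landforms and NDVI Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An object-based image analysis (OBIA) pipeline for mapping polygonal
    tundra geomorphology from 30 m multispectral reflectance rasters, together
    with per-pixel robust NDVI trend estimation and thematic-map accuracy
    assessment. Provides spectral indices (NDVI, NDWI, BlueMax, broadband
    albedo), region-merging image segmentation with object shape statistics, a
    rule hierarchy classifying image objects into fifteen wet-to-dry landform
    classes (coastal saline water, lakes by size, rivers, ponds, ice-wedge
    polygon types, drained thaw-lake basins, sandy barrens and dunes, drained
    slopes), Theil-Sen slope/intercept estimation with rank-based 95%
    confidence intervals and multi-sensor bias diagnostics, stratified
    reference sampling with confusion-matrix statistics (overall, user and
    producer accuracy, Cohen's kappa), and a synthetic-landscape generator so
    the whole pipeline is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
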