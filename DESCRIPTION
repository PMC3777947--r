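Package: shoremapper
Title: Kite Aerial Photogrammetry and Multispectral Mapping of Intertidal Shores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale photogrammetric pipeline for turning overlapping
    colour and near-infrared aerial photographs of an intertidal shore into a
    geo-referenced three-dimensional terrain model, colour and near-infrared
    orthomosaics, elevation, slope and aspect rasters, and a Normalised
    Difference Vegetation Index (NDVI) map.  Includes local invariant feature
    extraction and cross-band matching, epipolar outlier rejection,
    incremental structure-from-motion with self-calibrating bundle
    adjustment, patch-correlation densification, ground-control-point
    geo-registration (triad scale recovery plus Horn absolute orientation and
    a tidal-datum vertical correction), Delaunay terrain surfacing, best-four
    view texturing, camera spectral-response estimation and white-balanced
    NDVI products.  A synthetic-scene renderer with known ground truth stands
    in for kite imagery so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    pracma,
    igraph,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
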