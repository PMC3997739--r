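Package: coralhsm
Title: Deep-Sea Coral Habitat Suitability Modelling from Depth-Binned
    Climatologies
Version: 0.1.0
Authors@R:
    person("Coral", "HSM Maintainers", email = "coralhsm@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for presence-background habitat
    suitability modelling of deep-sea corals on a planar 500 m analysis
    grid: gridding of scattered bathymetric soundings with coarse-grid
    infill and multi-window Horn slope, conversion of depth-binned ocean
    climatology volumes into continuous seafloor rasters with water-bottle
    validation and correlation pruning, four-rule quality control of coral
    presence records, a from-scratch L1-regularized maximum-entropy
    (Maxent-style) model with logistic habitat suitability output and
    jack-knife variable importance, spatially partitioned four-region
    cross-validation with AUC-based fold retention and thresholded
    consensus mapping, and overlap accounting against protected-area
    polygons, substrate classes and trawl-intensity surfaces.  A synthetic
    seascape generator with known ground truth exercises every stage
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
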