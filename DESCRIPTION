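Package: midgutCa
Title: Cell-Type-Resolved Calcium Imaging Analysis for Epithelial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of intercellular calcium dynamics in an
    epithelial organ imaged with genetically encoded indicators. Provides a
    synthetic-tissue movie simulator (typed cell mosaic, gap-junction-coupled
    stochastic spiking, indicator kinetics, TIFF rendering), ROI trace
    extraction with centroid tracking, F/F_min normalization and
    prominence-based peak detection, per-cell and per-gut oscillation
    frequency summaries, lagged cross-correlation for finite time series
    anchored to the Pearson correlation at lag zero, and kymograph plus
    multicellular wave detection with extent, direction and path
    cell-type composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    ggplot2,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
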