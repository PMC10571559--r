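Package: clonoscope
Title: High-Content Clonogenic Survival Assay Analysis from Whole-Well Tile Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of high-content, high-throughput clonogenic
    survival assays imaged as multi-channel fluorescence tile scans.
    Provides clone-guided tile stitching with illumination/background
    correction, threshold-and-watershed nucleus segmentation with per-nucleus
    feature extraction, decision-tree classification of fluorescent RGB
    barcode color classes, density-based (DBSCAN) clone calling, clone- and
    nucleus-level survival statistics (plating efficiency, surviving
    fraction, DNA-content histograms, anomaly fractions), and multi-treatment
    screen analytics (normalized metrics, clone-size heterogeneity,
    hierarchical treatment clustering, metric-survival correlation). Includes
    a synthetic plate-image generator with exhaustive ground truth so every
    pipeline stage can be validated against a known world.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    FNN,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
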