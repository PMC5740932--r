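Package: phenotray
Title: Growth Phenotyping from Top-View Tray and Pot Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch analysis of top-view RGB image series of plant trays and
    pots. Images are calibrated to metric units via red circular fiducial
    markers of known physical radius, leaf regions are segmented by fusing a
    vegetative-greenness (ExG - ExR) k-means classification with a Lab
    colour-opponent segmentation, the tray is partitioned into a pot lattice,
    and per-pot growth traits are measured over time: projected leaf area,
    perimeter, convex-hull metrics, stockiness, compactness, greenness, daily
    relative growth rate, and leaf counts from skeleton end-points combined
    with centroid-to-contour distance-series peak detection. Results are
    written as per-series CSV trait tables. A synthetic tray-image generator
    with exact ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    parallel,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
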