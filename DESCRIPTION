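Package: cordnet
Title: Quantification of Endothelial Cord Network Formation from
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinematic quantification of endothelial cord/tube network
    formation in Matrigel tube-formation assays. Implements a per-frame
    analysis chain for time-lapse grayscale microscopy: contrast-limited
    adaptive histogram equalization, growth-boundary cropping, gaussian
    blurring and binarization, topology-preserving skeletonization by
    iterated erosion that stops prior to disconnection, conversion of the
    skeleton to a planar graph, and measurement of the distribution of
    areas enclosed by fully connected network cycles (the contour-area
    metric, in arbitrary units). Ships a synthetic Voronoi cord-network
    image generator with exact planar-graph ground truth (vertices, edges,
    bounded faces and their areas), a nested edge-dropout degradation axis
    emulating passage-dependent loss of network complexity, and replicate
    series comparison with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    readr,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
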