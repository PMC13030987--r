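Package: spatcube
Title: Spatial Statistics for 3D Cell Distributions on Cube-Discretized Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-detection analysis of large 3D fluorescence images of tissue
    (bone marrow in particular). Aggregates per-slice 2D bounding-box cell
    detections into 3D cell locations, discretizes the imaged volume into
    cubes with per-class cell counts, and quantifies spatial organisation:
    Moran's I spatial autocorrelation on the face-adjacency cube graph,
    quartile-thresholded density clustering into contiguous high-density
    regions, cluster-versus-surround permutation tests with Holm-Bonferroni
    correction, presence/absence logistic models, and quartile-neighborhood
    composition classification. Includes a synthetic tissue simulator
    (Poisson, Thomas-cluster and hardcore point processes sliced into noisy
    per-layer detections) so the whole pipeline can be exercised and
    benchmarked without microscope data, plus IOU-based detection evaluation
    with precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
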