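Package: nervetopo
Title: Nerve-Based Topological Analysis of 3D Cell-Resolution Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying differences in the 3D cellular
    architecture of segmented tissues. Builds the nerve simplicial complex of a
    labeled segmentation volume, summarises each cell by the face-vector of its
    vertex star, turns cohorts of samples into proportion feature vectors, and
    compares cohorts with the Baringhaus-Franz (Cramer) multivariate two-sample
    test with bootstrap p-values. Also provides comparative morphometrics
    (coefficient of variation of cell volume, stage-wise relative growth, tissue
    proportion shares, staging-threshold extrapolation, mitotic-division
    tallies) and a synthetic tessellation generator (bulk and weighted Voronoi,
    layered sheets, hexagonal fixtures) with ground-truth seeds, so that every
    analysis step can be exercised and validated without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
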