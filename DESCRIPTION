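Package: scapd
Title: Agent-Based Models of Stem-Cell Patterning on Micropatterns and
    the SCAPD Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates colonies of embryonic stem cells confined on disc or
    ellipse micropatterns with an agent-based model built from four motility
    rules (differential velocity, directional persistence, neighbour
    push/pull forces, border turning), enumerated as sixteen rule
    combinations plus a velocity-ratio refinement. Quantifies agreement
    between simulated and reference colony patterns with the stem cell
    aggregate pattern distance (SCAPD): per-cell-type kernel density maps
    with diffusion (Botev) bandwidth selection, mid-range thresholding,
    iso-contour extraction, least-squares circle and ellipse fitting,
    symmetrisation, and total-density integration inside the fitted
    high-density-area borders. Includes earth mover's distance,
    Kullback-Leibler divergence and ensemble CRPS baselines, exhaustive
    grid-search parameter calibration, and a generator of synthetic
    reference colonies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
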