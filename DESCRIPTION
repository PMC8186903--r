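Package: somatomap
Title: Topographic Finger-Map Analysis for Somatosensory Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fine-grained topographic finger maps in
    primary somatosensory cortex from surface-sampled fMRI and matched
    psychophysics. Implements phase-encoded (travelling-wave) Fourier
    mapping with mirror-run averaging and stimulus-frequency F-ratios,
    one-dimensional Gaussian population receptive field (pRF) modelling,
    surface-mesh map geometry (vertex areas, geodesic and Euclidean
    inter-digit distances, dice overlap), between-run representational
    similarity with digit-neighbour summaries, finger mislocalization and
    two-point discrimination analyses (neighbour-weighted chance model,
    G-tests, signal-detection measures), and group-level statistics
    (bootstrap Hedges' g, TOST equivalence with power-derived bounds,
    iterative factor-model variable exclusion). A seeded synthetic-data
    generator produces stimulus designs, cortical patches, BOLD and
    resting-state series, and behavioural trial tables with known ground
    truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
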