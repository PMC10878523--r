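Package: firescape
Title: Fire-History Reconstruction and Post-Fire Forest Structure from Satellite Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs multidecadal fire history in tropical dry forest from
    monthly optical satellite composites and quantifies fire effects on
    lidar-derived canopy structure. Detects burns by matching dated negative
    structural breaks in per-pixel NDVI season-trend models (BFAST-style
    piecewise-linear trend with harmonic seasonality) against spikes in the
    differenced normalized burn ratio (dNBR), groups burned pixels into dated
    fire-event polygons with a minimum mapping unit, refines perimeters by
    object-based classification (SLIC segmentation plus a small feed-forward
    classifier), accumulates per-pixel burn-count and time-since-fire layers,
    and tests burn-history effects on plant area index, canopy cover and
    canopy height with rank-based tests and linear mixed models. Includes a
    seeded synthetic-scene generator with a ground-truth fire catalog so the
    whole pipeline can be validated against a known oracle.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    nnet,
    lme4,
    lmerTest,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
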