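Package: cbctiq
Title: Simulation and Image-Quality Analysis for Megavoltage Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how acquisition protocol choices (arc length,
    number of projections, total exposure) affect megavoltage cone-beam CT
    image quality. Provides voxelized attenuation phantoms with ground-truth
    region labels, a fan-beam scan simulator with monitor-unit-scaled Poisson
    exposure noise, filtered backprojection with short-scan (Parker)
    redundancy weighting, the standard phantom image-quality metrics
    (uniformity, noise, contrast-to-noise ratio per insert, and the
    edge-spread-function based modulation transfer function with its 50%
    frequency), protocol logistics arithmetic (MU per projection, sampling
    rate, acquisition time, projection storage), and an experiment driver
    that sweeps a set of protocols and renders summary tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
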