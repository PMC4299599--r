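Package: fccstools
Title: Simulation and Quantitative Analysis of FCS/FCCS Photon-Count Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dual-color fluorescence (cross-)correlation
    spectroscopy (FCS/FCCS) of cytoplasmic proteins. Includes a
    Brownian-dynamics simulator of two-channel confocal photon-count traces
    (3D-Gaussian detection volumes, triplet blinking, photobleaching,
    background and spectral crosstalk), a multi-tau correlator with
    bleach detrending and artifact-segment rejection, weighted fitting of
    free and anomalous diffusion models with triplet correction,
    calibration of observation volumes from reference dyes, and conversion
    of fitted parameters into per-cell concentrations, diffusion
    coefficients, molecular brightness (counts per particle per second),
    complex concentrations and apparent dissociation constants, with
    per-strain aggregation into a quantitative interaction network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    igraph,
    yaml,
    data.table,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
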