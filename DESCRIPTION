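Package: thzchem
Title: Terahertz Spectroscopy Chemometrics with Interval Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chemometric analysis of terahertz time-domain
    spectroscopy (THz-TDS) for discriminating labelled sample classes such as
    crop varieties. Provides a forward simulator of reference and sample
    time-domain traces for classes with prescribed absorption profiles,
    extraction of optical constants (refractive index and absorption
    coefficient) from the sample/reference transfer function of a thin
    pellet, a from-scratch NIPALS partial least squares (PLS1) regression
    with leave-one-out cross-validation, equal-width interval PLS (iPLS)
    variable selection by minimum RMSECV, and a seeded end-to-end pipeline
    producing calibration/prediction reports.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
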