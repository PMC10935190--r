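Package: silagescan
Title: Whole-Plant Corn Moisture from Handheld NIR Ear Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for estimating standing whole-plant corn
    moisture from near-infrared reflectance scans of intact ears. Provides
    a SummarizedExperiment-based container for multi-instrument spectra,
    reflectance-to-absorbance conversion and replicate averaging, the
    standard pretreatment family (autoscaling, multiplicative scatter
    correction, Savitzky-Golay derivatives) with a grid-search optimizer,
    single-response partial least squares regression with Venetian-blinds
    cross-validation and first-local-minimum latent-variable selection,
    full calibration/validation statistics (SEC, SECV, SEP, bias, RPD and
    its performance classes), a quadratic ear-to-whole-plant moisture
    chain, a multi-instrument calibration-transfer experiment, and a
    synthetic spectra generator that emulates a two-season field campaign
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
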