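Package: specfat
Title: Fatty-Acid Calibration from Raman and Near-Infrared Spectra of Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fatty-acid composition in muscle tissue
    from vibrational spectra. Implements the full calibration workflow:
    simulation of fatty-acid compositions and Raman-like or near-infrared-like
    spectra with known ground truth, spectral preprocessing (standard normal
    variate, extended multiplicative signal correction with polynomial
    extension, baseline correction, replicate averaging), single-response
    partial least squares regression with venetian-blind cross-validation,
    region-of-interest and bottom-up block variable selection, iodine value
    and fatty-acid feature computation, and covariance-structure diagnostics
    for the "cage of covariance" that couples predictions of correlated
    analytes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
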