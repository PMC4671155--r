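Package: hayNIRS
Title: Near-Infrared Calibration of Forage Quality by MLR, PCR and NIPALS-PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration of forage-quality constituents (crude
    protein, acid and neutral detergent fiber) from near-infrared reflectance
    spectra in the 950-1650 nm range. Provides a seeded synthetic-data
    generator for hay-like spectra with known chemistry, spectral
    preprocessing (absorbance transform, replicate averaging, normalization,
    Savitzky-Golay and Norris gap-segment second derivatives), Mahalanobis
    outlier screening in principal-component score space, three calibration
    engines (two-wavelength multiple linear regression with
    correlation-spectrum selection, principal component regression, and
    NIPALS partial least squares), leave-one-out component selection, and a
    validation layer computing RMSEC, RMSEP, calibration and validation
    coefficients of determination, and RPD quality bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
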