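Package: wetspec
Title: Calibration Pipeline for Handheld NIRS of Undried Forage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating partial least squares (PLS-1)
    calibrations of forage constituents (crude protein, fiber fractions,
    digestibility) from near-infrared reflectance spectra of undried haylage
    acquired with handheld instruments. Provides wide-CSV spectral I/O with
    resampling to a common wavelength grid, log(1/R) absorbance conversion,
    general least-squares Savitzky-Golay derivative filtering (including even
    window lengths), a from-scratch NIPALS PLS-1 implementation with
    per-latent-variable explained variance and loading spectra, Q-residual and
    Hotelling T-squared outlier screening at configurable confidence, bunker
    (group) aware train/validation splitting and k-fold cross-validation,
    latent-variable selection by grid search, RPD-based evaluation metrics with
    Malley and Williams classification tiers, water absorption band analysis of
    loading spectra, and a seeded generator of synthetic multi-instrument,
    multi-scan-mode haylage-like spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
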