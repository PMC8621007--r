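Package: nirmilk
Title: Chemometric Calibration of Miniature NIR Spectrometers for Raw-Milk
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for calibrating near-infrared (NIR)
    milk-composition analyzers: white/dark standard correction and scan
    averaging, a 420-combination spectral preprocessing grid (log transform,
    baseline/detrend/SNV/MSC, Savitzky-Golay derivatives, orthogonal signal
    correction, mean centering), cow-blocked duplex partitioning into
    calibration and validation sets, partial least squares regression with
    statistically parsimonious latent-variable and preprocessing selection
    (one-sided paired t-tests on cross-validated absolute residuals), four
    wavelength-selection algorithms (VIP, jack-knife, reversed and forward
    interval PLS), and evaluation against ICAR accuracy limits and Williams
    R-squared classes, including a two-way ANOVA plus Tukey HSD comparison of
    instruments.  A synthetic raw-milk spectra generator with Beer-Lambert
    component absorption, within-cow clustering, scatter effects and detector
    noise makes every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
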