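Package: cyclofit
Title: Conformational Stability and Prolyl-Isomerase Kinetics from Optical
    Spectroscopy Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein conformational stability and
    peptidyl-prolyl cis/trans isomerase (PPIase) catalytic activity from
    optical spectroscopy recordings. Normalizes circular-dichroism spectra
    to mean residue ellipticity, converts refractive-index readings to
    urea concentrations, fits two-state equilibrium unfolding transitions
    by the linear extrapolation method with derived transition midpoints,
    decomposes fluorescence relaxation traces into exponential phases with
    information-criterion model selection, and estimates specificity
    constants (kcat/KM) by linear regression of apparent isomerization
    rates on enzyme concentration. Includes a seeded synthetic-data
    generator for unfolding titrations and full isomerization assays with
    known ground truth, so every analysis stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
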