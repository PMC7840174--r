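Package: clampresp
Title: Window-Based Drug-Response Analysis for Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for drug responses in whole-cell voltage-clamp
    holding-current recordings. Bins holding-current time series, classifies
    per-cell drug responses (outward/inward/none) by comparing fixed baseline
    and drug windows with Student's t test, validates classifications with a
    Bonferroni-corrected sliding-window analysis, quantifies receptor
    desensitization from repeated agonist applications, fits Hill
    concentration-response curves (EC50), and runs permutation tests on group
    means and standard deviations. Includes a synthetic trace generator with
    known ground truth for calibration, and a minimal module for quantifying
    stimulated dopamine transients recorded with fast-scan cyclic voltammetry
    (background subtraction, peak amplitude, percent-of-baseline effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
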