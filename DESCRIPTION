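Package: secsaxs
Title: Decomposition and Baseline Correction of SEC-SAXS Elution Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing size-exclusion chromatography coupled
    small-angle X-ray scattering (SEC-SAXS) frame series. Converts a
    time-ordered set of background-subtracted scattering curves into
    per-q chromatograms, detects and corrects capillary-fouling
    baselines with an iterative integral method, decomposes poorly
    resolved elution peaks into symmetric or skewed Gaussian components
    (EMG, GMG and their hybrid) through a global fit across q, and
    extracts per-species scattering curves with propagated
    uncertainties, per-frame concentrations, Guinier parameters and
    molecular-mass estimates. Curve-similarity decisions throughout are
    guided by longest-run (correlation-map) P values with optional
    Holm-Bonferroni adjustment. A fully specified synthetic-data
    generator reproduces the statistical structure of fouled,
    poorly-resolved elution series so that every step can be validated
    without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
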