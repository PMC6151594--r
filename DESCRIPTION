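Package: vinelements
Title: Simulated ICP-MS Elemental Profiling of Wine and Sample-Preparation
    Method Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inductively coupled plasma mass spectrometry (ICP-MS)
    elemental profiling of wine: a synthetic instrument-batch generator
    emulating four sample-preparation treatments (direct dilution, two
    filtration variants, and microwave-assisted acid digestion), external
    calibration with internal-standard normalization, blank-based detection
    limits with left-censoring at half the detection limit, quality-control
    and spike-recovery checks, isotope-dilution quantitation of copper from
    the 63Cu:65Cu response ratio, and the method-comparison statistics
    (MANOVA gate, per-isotope ANOVA with Tukey letter displays,
    blank-compromise channel exclusion, and correlation-matrix PCA of
    elemental profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
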