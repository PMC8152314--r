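Package: coronet
Title: Morphometry of Coronary Resistance-Artery Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ring-unit morphometry of traced coronary resistance-artery
    networks. Decomposes rooted planar arterial trees into 50-micrometre
    cylindrical ring units, analyses bifurcations against Murray's law and
    the branching-angle/radius-ratio relation, builds ring-frequency spectra
    by outer-diameter class and bidimensional diameter-by-flow-distance
    histograms with chi-squared group comparison, profiles wall thickness
    against diameter with two-way ANOVA and Tukey post hoc tests, and
    computes echocardiographic left-ventricular mass and function indices
    (cube formula, fractional shortening, Teichholz volumes, ejection
    fraction). Includes a seeded generator of synthetic coronary-like trees
    with sex/training group presets so the whole pipeline is testable
    without traced specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
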