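Package: fenceroo
Title: Cross-Fence Kangaroo Demography, Growth, Morphometrics, and
    Vegetation Anomalies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for comparing two red kangaroo (Osphranter
    rufus) populations separated by the dingo barrier fence: molar-index
    age estimation, sex-ratio and age-structure demography, von
    Bertalanffy growth-curve fitting with grouped parameter contrasts,
    generalized Procrustes analysis of 3D cranial landmarks with
    bilateral-symmetry decomposition and residual-randomization
    permutation linear models, and seasonal standardized vegetation-index
    anomalies with a randomization test on the between-site median
    difference. A synthetic-data generator reproduces the statistical
    structure of the field data so the whole pipeline runs end to end
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
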