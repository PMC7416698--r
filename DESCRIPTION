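Package: fovecast
Title: Predicting Foveal Visual Potential from Photoreceptor Structure on OCT
Version: 0.1.0
Authors@R:
    person("Foveal", "Imaging Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting foveal visual function (light-adapted foveal
    sensitivity and best-corrected visual acuity) from foveal photoreceptor
    structure measured on optical coherence tomography (OCT), and for turning
    those predictions into per-patient treatment potential in blue cone
    monochromacy. Includes a synthetic B-scan and cohort simulator, a
    longitudinal-reflectivity-profile segmentation pipeline for six outer
    retinal boundaries, random-forest regression models on segmentation and
    reflectivity features with leave-one-subject-out validation, a
    quantum-catch logarithmic structure-function curve fit, ETDRS visual
    acuity arithmetic, and group comparison via the Kruskal-Wallis rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
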