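Package: cardiofem
Title: Finite-Element Estimation of Regional Left-Ventricular Contractility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-informed cardiac biomechanics toolkit for estimating regional
    left-ventricular (LV) passive stiffness and contractility from end-systolic
    strains and cavity volumes. Provides an idealized truncated prolate-spheroid
    hexahedral LV mesh generator with rule-based myofiber architecture and AHA
    17-segment labeling, a transversely isotropic exponential (Guccione-type)
    passive law with a time-varying-elastance active stress, implicit
    quasi-static Newton solves for diastolic inflation and end-systolic
    contraction, sector-wise material maps driven by late-gadolinium-enhancement
    (LGE) and stress-perfusion (SP) scores, a two-stage inverse scheme that
    calibrates healthy stiffness against end-diastolic volume and recovers
    healthy contractility together with an ischemia-effect parameter from
    strain/volume targets, and a virtual-revascularization counterfactual.
    Includes a synthetic-data module that forward-simulates "experimental"
    targets with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
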