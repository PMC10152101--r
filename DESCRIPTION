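Package: fetoconn
Title: Fetal Functional Connectome Development Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the in-utero development of functional
    thalamocortical and cortico-cortical connectivity from fetal resting-state
    fMRI at the region-of-interest level. Implements outlier-volume rejection,
    aCompCor nuisance regression with simultaneous high-pass filtering,
    censored Pearson connectivity matrices, Riemannian (SPD tangent-space)
    quality control with an iterative age-consistency filter, sigmoid
    growth-curve fitting of edge trajectories with bootstrap and permutation
    inference, hemispheric homolog-similarity and laterality-index statistics,
    and a synthetic fetal BOLD cohort generator with known connectivity ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
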