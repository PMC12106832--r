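Package: perigyri
Title: Perinatal Gyrification Trajectories and Regression Discontinuity at Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the effect of birth on cortical folding
    during the perinatal period (21-45 weeks post-conception). Implements a
    mesh-based 3D gyrification index (surface area over convex-hull area) for
    triangulated cortical surfaces, quadratic developmental-trajectory fits,
    a sharp regression-discontinuity estimator at a term-birth cutoff using
    local polynomial regression with triangular kernel weights and
    bias-corrected robust inference, a growth-partition statistic splitting
    total perinatal growth into fetal, birth-jump and postnatal shares, and
    sensitivity analyses (scanner ANOVA, sex-stratified discontinuity models,
    preterm trajectory overlay). A synthetic cohort generator emulates the
    statistical structure of a large fetal/neonatal MRI sample so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
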