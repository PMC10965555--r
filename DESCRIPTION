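Package: aortamech
Title: Biaxial Mechanics and Allometric Classification of the Murine Ascending Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for passive inflation-extension testing of the
    murine ascending thoracic aorta. Implements an incompressible four-fiber-family
    hyperelastic constitutive model (isotropic matrix plus axial, circumferential,
    and two symmetric diagonal fiber families) with analytic Cauchy stress and
    small-on-large linearized stiffness; reduction of raw pressure-diameter and
    force-length records to wall geometry, biaxial stretch, and mean wall stress;
    estimation of the in-vivo axial stretch from the force-invariance point;
    multi-start nonlinear least-squares parameter fitting; derived in-vivo metrics
    at diastolic and systolic pressures including cyclic distensibility and stored
    energy; allometric scaling of luminal diameter with body mass with
    prediction-interval dilatation and aneurysm classification; Spearman
    rank-correlation cohort statistics; and a seed-deterministic synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
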