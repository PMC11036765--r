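Package: kneestrain
Title: Reduced-Order Knee Model for ACL Strain During Single-Leg Jump Landing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, reduced-order model of the tibiofemoral joint for
    studying anterior cruciate ligament (ACL) strain. Bones are rigid bodies,
    ligaments are tension-only nonlinear one-dimensional elements with the
    piecewise quadratic-linear (Blankevoort) force law, and articular contact
    is a frictionless penalty on simple surface primitives. The package ships
    quasi-static and explicit-dynamic solvers, scripted reproductions of the
    classic passive-motion validation protocols (flexion sweep, Lachman,
    anterior drawer, abduction), a synthetic generator of single-leg
    jump-landing boundary-condition profiles, a landing simulator reporting
    peak relative ACL strain with a touch-down gauge length, and the
    statistical pipeline (z-normalisation, bivariate Pearson screening,
    Box-Cox transformation, multivariate regression) that produces an
    empirical peak-strain equation from sagittal-plane landing descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
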