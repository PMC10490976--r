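Package: cornvec
Title: Corneal Power Vector Analysis for Toric IOL Eyes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing corneal power in cataract surgery with toric
    intraocular lens implantation. Converts keratometric, tomographic and
    refraction measurements from meridional (radius/power plus axis) notation
    into power vector components (equivalent power EQ and the double-angle
    astigmatism projections C0 and C45), applies left-eye mirroring, and
    supports vector arithmetic between devices and time points. Provides a
    cohort CSV pipeline with quality-based exclusion rules, descriptive
    summary and difference panels, bivariate confidence ellipses for
    double-angle plots, and two predictors of postoperative total corneal
    power from preoperative keratometry: a multivariate linear regression and
    a shallow feedforward network trained with the Levenberg-Marquardt
    algorithm. A synthetic cohort generator with a configurable ground truth
    makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
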