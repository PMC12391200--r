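Package: discmech
Title: Regional Biphasic Mechanics of Intervertebral Disc Tissue
Version: 0.1.0
Authors@R:
    person("Disc", "Mechanics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the biphasic (poroelastic) mechanics of
    cervical intervertebral disc tissue regions (nucleus pulposus, annulus
    fibrosus, cartilaginous endplate). Implements closed-form linear biphasic
    solutions for confined-compression creep and stress relaxation, a
    finite-difference consolidation solver used as an independent oracle,
    nonlinear least-squares estimation of aggregate modulus and hydraulic
    permeability from creep traces, swelling pressure and buoyancy-porosity
    calculations, ideal Donnan osmotic swelling with deformation-dependent
    fixed charge density, a quasi-static displacement-pressure hexahedral
    finite element solver for an idealized three-region disc under unconfined
    compression, a synthetic dynamic-mechanical-analysis cohort generator with
    instrument quantization, and a regional statistics pipeline (one-way
    ANOVA, Holm-adjusted pairwise Welch tests, Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
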