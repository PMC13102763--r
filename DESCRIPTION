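Package: trajtargets
Title: Vital-Sign Trajectory Phenotyping and Model-Derived Blood Gas Target Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Phenotypes critically ill patients by group-based multi-trajectory
    modeling of multi-channel vital signs over the first hours of intensive
    care, quantifies subgroup mortality risk with Cox proportional-hazards
    contrasts and covariate-adjusted survival curves, models nonlinear blood
    gas dose-response with restricted cubic splines, and extracts lowest-risk
    ("safe zone") blood gas ranges from random-forest partial dependence within
    the high-risk subgroup. Includes a seeded synthetic-cohort generator with
    known latent structure, a preprocessing protocol (plausibility filtering,
    winsorization, hourly aggregation, gap imputation, standardization), and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
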