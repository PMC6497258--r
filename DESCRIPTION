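Package: pregphys
Title: Empirical Models of Maternal and Fetal Physiology During Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A repository of empirical models describing anatomical and
    physiological changes in an average human mother and her fetus during
    pregnancy and gestation, intended for parameterizing physiologically
    based pharmacokinetic (PBPK) models.  Provides closed-form growth-curve
    models (polynomial, Gompertz, logistic, allometric power-law families)
    for maternal and fetal compartment volumes, blood flow rates (including
    the fetal ductus arteriosus, ductus venosus and foramen ovale shunts),
    hematocrits and glomerular filtration rate as functions of gestational
    age, together with mass-balance and flow-conservation composites for
    "rest of body" compartments.  Also implements the maximum-likelihood
    calibration machinery used to construct such models from summary-
    statistic data (means, standard deviations and sample sizes), with
    AIC-based model selection and a nonnegativity feasibility screen, plus
    a synthetic summary-data generator for testing parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
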