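Package: adipolife
Title: Multistate Life Tables for Adiposity and Life Expectancy with and
    without Cardiovascular Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating total, cardiovascular-disease-free, and
    with-disease life expectancy by adiposity category in longitudinal
    cohorts, using a three-state illness-death model.  Transition rates
    (disease-free to disease, disease-free to death, disease to death) are
    modelled as Gompertz proportional hazards fitted by Poisson regression
    on age-split person-time with cluster-robust standard errors.
    Category-specific rates are recovered from overall rates, adjusted
    hazard ratios, and observed category prevalences, and propagated
    through a cohort multistate life table closed at age 80.  Percentile
    confidence intervals come from a parametric bootstrap.  A synthetic
    cohort generator with composite body-mass-index and waist-circumference
    adiposity phenotyping makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    sandwich,
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
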