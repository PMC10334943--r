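Package: phenoforge
Title: Phenotype Algorithm Construction, Diagnostics and Probabilistic
    Validation for Observational Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A cohort-definition engine over a simplified OMOP-style
    longitudinal data model, built around four hidradenitis suppurativa
    phenotype algorithms (incident and prevalent, one-code and
    two-code variants).  Provides cohort characterization statistics
    (incidence rates per 100,000 person-years, cohort overlap,
    index-code breakdown, standardized-mean-difference covariate
    comparison), a probabilistic reference-standard evaluation pipeline
    that estimates sensitivity, specificity, PPV and NPV from a
    regularized diagnostic prediction model without chart review, and a
    synthetic claims-data simulator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
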