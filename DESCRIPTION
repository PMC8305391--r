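Package: trajclass
Title: Latent-Class Trajectory Stratification of Functional Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint latent-class modelling of long-term functional recovery
    trajectories in pediatric acquired brain injury cohorts. Fits a K-class
    mixture in which baseline covariates drive class membership through a
    multinomial-logit submodel, each class follows a polynomial mean
    trajectory for a bounded functional score (FIM/WeeFIM), and attrition
    from follow-up enters the likelihood through class-specific
    discrete-time exit hazards. Provides multi-start EM estimation with BIC
    model selection, split-half stability testing with likelihood-ratio
    tests, cross-design (held-out) class assignment, single-subject
    prediction of trajectory class from first-discharge data with nested
    cross-validation, and a synthetic-cohort generator with ground-truth
    labels for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust,
    nnet,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
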