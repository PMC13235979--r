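Package: puprev
Title: Positive-Unlabeled Prevalence Estimation for Undercoded Phenotypes
Version: 0.1.0
Authors@R:
    person("puprev", "maintainers", email = "puprev@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of phenotypes that are documented in
    clinical records but missing from structured diagnosis codes, using
    positive-unlabeled (PU) learning on sparse binary covariate matrices.
    Implements balanced-undersampling PU ensembles with cross-fitted
    classifier scores, class-prior (mixture proportion) estimation under the
    selected-completely-at-random (SCAR) assumption and a subtype-clustering
    extension for selected-not-at-random (SNAR) labeling, alpha-anchored
    probability calibration, probability-bin chart-review audit design,
    bias-only logit-shift post hoc calibration with percentile-bootstrap
    confidence intervals, inter-rater agreement statistics (Cohen and Fleiss
    kappa, Monte-Carlo Fisher exact tests), cohort characterization (odds
    ratios, proportion confidence intervals), and prevalence report assembly.
    A synthetic-cohort generator with latent positive subtypes provides
    ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    stats,
    utils,
    graphics,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
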