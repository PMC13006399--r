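Package: dtmr
Title: Drug-Target Mendelian Randomization for Treatment-Response Cohorts
Version: 0.1.0
Authors@R:
    person("CAPOC", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for drug-target genetic association analysis of
    treatment efficacy in clinical cohorts: genotype and sample quality
    control with an auditable exclusion cascade, construction of weighted
    drug-target genetic risk scores (GRS) with instrument-strength statistics
    (R-squared, F), covariate-adjusted one-sample analyses including
    two-stage least-squares causal estimation, stratified and factorial
    Mendelian randomization, mediation by conditioning, two-sample MR
    estimators (IVW, weighted median, MR-Egger, a PRESSO-style outlier
    test), Bayesian colocalization via Wakefield approximate Bayes factors,
    and regression diagnostics (Breusch-Pagan, White, HC3, influence, VIF).
    Ships a synthetic-cohort generator with known ground truth so every
    stage is testable without access-restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
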