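Package: dbmtransit
Title: Multi-State Transition Analysis of the Double Burden of Malnutrition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying longitudinal transitions between four
    nutritional states (normal, stunted, overweight, and concurrently
    stunted and overweight) in child and adolescent cohorts. Classifies
    subject-round records from anthropometric z-scores using WHO-style
    age-dependent cutoffs, fits time-inhomogeneous first-order Markov
    chains by closed-form maximum likelihood with per-interval transition
    matrices and marginal state trajectories, and quantifies covariate
    effects on transitions into and out of each malnourished state with
    binary logit transition models reported as odds ratios. Includes a
    synthetic longitudinal cohort simulator with known truth (covariate
    effects on the logit scale, monotone attrition, state-consistent
    anthropometry) so the full pipeline can be validated by parameter
    recovery, plus complete-case preparation, baseline descriptive tables
    with chi-squared tests, univariate screening and stepwise AIC model
    selection, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
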