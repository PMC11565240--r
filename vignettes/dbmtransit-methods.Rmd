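---
title: "Methods: multi-state transition modelling of the double burden of malnutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-state transition modelling of the double burden of malnutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmtransit)
```

## Scope and assumptions

`dbmtransit` models the nutritional trajectory of a cohort observed at a
small number of assessment rounds as a discrete-time, first-order,
four-state Markov chain over {normal, stunted, overweight, cso}. Three
assumptions do the work:

1. **First-order dependence.** The state at round t+1 depends on the past
   only through the state at round t. Longer memory (e.g. scarring from
   early stunting) is absorbed into the current state.
2. **Time-inhomogeneity.** Each between-round interval gets its own
   transition matrix. With rounds spaced years apart over childhood and
   adolescence this is essential: stunting onset concentrates in early
   childhood while reversal peaks in adolescence, so a single matrix
   would average away exactly the age structure of interest.
3. **Fully observed states.** States come from measured anthropometry,
   not from a latent process. This is why the MLE is closed form
   (`P_ij(t) = n_ij(t)/n_i(t)`) and why no latent-chain machinery (EM,
   forward–backward) appears anywhere: for observed chains the saturated
   time-inhomogeneous MLE *is* the empirical transition frequency. A
   consequence worth exploiting in tests is the saturated-model identity:
   marginals propagated from the empirical baseline distribution equal
   the empirical round-wise state frequencies exactly, on every
   complete-case panel.

The complete-case restriction (subjects present in all rounds with
classifiable anthropometry, listwise deletion for covariates) mirrors
standard practice for these models; it can bias estimates when dropout is
informative, which is why `attrition_comparison()` reports
included-vs-excluded baseline tables with chi-squared tests rather than
pretending the issue away.

## Classification rules

Cutoffs are strict inequalities: HAZ < −2 for stunting, and for
overweight WHZ > 2 under 5 years, BMI-for-age z > 1 at 5–19 years, BMI >
25 kg/m² over 19 years. A record exactly at a cutoff is *not*
malnourished. Age bands are half-open — [0, 5) uses WHZ, [5, 19] uses
BAZ, (19, ∞) uses BMI — with exactly 19 assigned to the BAZ band, since
growth references for BMI-for-age cover 5–19 inclusive. `cso` is the
conjunction of both criteria in the same round; `normal` the absence of
both; so the four states are mutually exclusive and exhaustive.

z-scores can be recomputed from raw measurements with the LMS transform
`z = ((x/M)^L − 1)/(L·S)`, switching to the analytic limit
`log(x/M)/S` when |L| < 1e-8 to keep the transform continuous in L.
Reference tables are user-supplied CSVs interpolated linearly in the key;
the package deliberately bundles no growth reference. Two known
limitations are *not* handled: the restricted-application adjustment some
references recommend for extreme weight-based z-scores (|z| > 3), and
pubertal-timing misclassification in adolescents who mature earlier or
later than the reference population.

## The two-state covariate models

Covariate effects are estimated on binary collapses of the chain rather
than on the full 4×4 chain: transitions between different malnourished
states are too rare in realistic cohort sizes to support a multinomial
covariate model, so each malnourished condition gets its own two-state
model with directions *into* and *out of* the state. The collapse keeps
marginal definitions — {stunted, cso} count as stunted, {overweight, cso}
as overweight — because CSO is by definition the conjunction of the two
conditions.

For each direction the model is
`logit P(in state at t+1 | origin, x_t) = α(t) + β'x_t`: one intercept
per interval, covariate effects shared across intervals (a single OR per
covariate — an overall estimate that cannot capture age-varying
associations, a recognised trade-off for power). Covariates are taken at
the origin round of each interval, so a wealth change between rounds
affects the transition it precedes, not the one it follows. Reference
categories are male, urban, ≤5 household members, poorest wealth quartile
(Q1), ≤6 years maternal education.

Estimation is damped Newton–Raphson on the Bernoulli log-likelihood
(`logit_newton()`): full Newton steps with halving until the likelihood
is non-decreasing, convergence at max |score| < 1e-8 or parameter change
< 1e-10, at most 100 iterations. For the canonical logit link the
observed information equals the expected information, and its inverse at
the optimum supplies the SEs; CIs are Wald at z = 1.96 (the conventional
default for logit parameterizations; profile intervals would differ only
in small samples where we flag non-estimability anyway). Two failure
modes are detected and reported instead of returning numbers: complete
separation (coefficients diverging past |β| > 15) and insufficient
information (fewer than 5 events or 5 non-events in a direction — the
CSO-exit direction in small cohorts is the canonical casualty). Flagged
directions propagate as explicit blanks with reasons through
`odds_ratio_table()`.

Model selection reproduces the usual workflow: univariate logistic
screening of candidates against baseline stunting and baseline overweight
(pass if any level has Wald p < 0.05 for either outcome), then greedy
forward addition ordered by total AIC (entry + exit), stopping when no
candidate lowers it. AIC rather than BIC because the comparison involves
modest samples and we prefer the milder complexity penalty. Ties within
1e-9 break lexicographically and are logged. The final reported model
defaults to the *fully adjusted* set, even when a smaller model edges it
on AIC in sparse targets, because cross-target comparability of ORs is
worth a few AIC points; `final = "best_aic"` switches this.

## The synthetic cohort generator

The generator exists so every downstream stage can be validated against
known truth. Its default configuration is a five-round younger cohort
measured at ages 1, 5, 8, 12, 15 with ~25% baseline stunting and ~3%
baseline overweight, stunting incidence front-loaded in the first
interval (0.22, falling to 0.04) and reversal rising with age (0.25 to
0.50), overweight incidence rising with age (0.05 to 0.10), per-round
dropout 2.5% (≈ 90% complete cases over five rounds) and 0.5% field-level
missingness — magnitudes typical of multi-round child cohorts in
countries undergoing nutrition transition. Defaults for the covariate
effects point the way such gradients usually point: wealth protective
against stunting entry (Q4 log-odds −0.9), promoting reversal (+0.6) and
overweight entry (+1.0); rural residence the reverse.

Two design choices matter for interpretation:

- **Product structure of the default matrices.**
  `product_transition_matrix()` builds each 4×4 matrix as the product of
  two independent binary chains — stunting status and overweight status.
  Consequently the probability of entering (leaving) the stunted group is
  identical from every origin outside (inside) it, and likewise for
  overweight. Combined with covariate modulation applied as a logit shift
  on exactly those group-entry/exit probabilities (remaining mass
  rescaled proportionally within each side, which preserves the product
  structure), the generating process *is* the model
  `fit_transition_logit()` estimates. Parameter recovery is therefore an
  identity check, not an approximation — bias in a recovery simulation
  indicates a bug, not misspecification. Effects on the `cso` target
  break the product structure (the cso-vs-rest split cuts across both
  chains), so cso-target recovery is approximate; user-supplied matrices
  without the product property likewise make the two-state models
  working approximations, as they are on real data.
- **Covariate dynamics.** Wealth quartile, residence and household size
  evolve by a sticky Markov process (stay probability 0.9, otherwise a
  uniform draw among the other levels); sex and maternal education are
  fixed. Real covariate dynamics are not this exchangeable — wealth
  transitions are locally ordered — but stickiness is what matters for
  the origin-round covariate convention being testable.

What the generator does *not* emulate: sentinel-site cluster sampling and
oversampling of poor areas (no survey weights anywhere in the package),
cohort-vs-age confounding, secular drift in food environments,
measurement error in height and weight, and informative dropout unless
explicitly configured through `dropout_effects`. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's
own assumptions — not robustness to the ways real cohorts violate them.

Ages are taken as the round's target age exactly; round-specific age
jitter (cohort protocols typically allow ±6 months) would only matter at
the 5- and 19-year band edges, and the classifier takes the row's own age
wherever it falls. Attrition is monotone by default (once gone, gone),
matching cohort attrition; intermittent missingness enters through
field-level blanking. A single seed in the config drives every draw:
`simulate_cohort()` seeds the R generator once and the anthropometry and
attrition stages continue the same stream, so a pipeline run is
reproducible end to end.

## Numerical choices and degenerate inputs

- Transition-matrix rows must sum to 1 within 1e-12 at config validation;
  fitted rows satisfy the same bound by construction.
- Origin states with zero subjects at a round produce *undefined*
  (all-NA, flagged) matrix rows, never zero-filled rows; propagation
  tolerates them only with zero occupancy mass, else errors.
- The truncated-normal anthropometry draws clamp at cutoff ± 1e-8 so a
  floating-point draw can never land exactly on a strict cutoff and break
  the round-trip contract.
- Chi-squared tests are plain Pearson without continuity correction
  (standard for r×c tables); expected counts below 5 set a flag on the
  result. Variables with a single observed level report p = NA rather
  than a fabricated value.
- Exclusion logging attributes each subject to its *first* failing reason
  in the fixed order missing round → missing anthropometry → missing
  covariate, so reason counts partition the excluded set.

## Problem sizes used in validation

The shipped validation suite simulates cohorts of 10 000 subjects (50
replicates) for odds-ratio recovery, 5 000 subjects (200 replicates) for
CI coverage, 10 000 subject-rounds for the classification round trip,
10 000 subjects for the attrition closed form, and 1 500-subject null
cohorts (100 replicates) for screening calibration — sizes chosen so
Monte-Carlo error is well below the effects being verified while a full
run stays in the minutes range on one CPU. Exact identities (oracle
equivalence, saturated-model marginals, AIC differences) are checked on
small fixtures where brute force is feasible.

## Known limitations

- No survey weights or design-based variance; estimates describe the
  analytic sample.
- Complete-case analysis only; no imputation. The attrition comparison
  quantifies, but does not correct, selective loss.
- A single OR per covariate per direction; age-varying covariate effects
  require stratified runs.
- The four-state chain is unadjusted; covariates act only through the
  two-state collapses, and the initial state distribution is
  covariate-free.
- No continuous-time modelling: intervals are treated as the process
  clock, so estimates are per-interval, not per-year.
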