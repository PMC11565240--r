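# dbmtransit

Multi-state transition analysis of the double burden of malnutrition in
longitudinal child and adolescent cohorts.

## The problem

In many low- and middle-income countries, chronic undernutrition
(stunting) and overnutrition (overweight) now coexist — sometimes in the
same child, as concurrent stunting and overweight (CSO). Cross-sectional
prevalence hides the dynamics: who becomes stunted, who recovers, who
progresses from stunting or overweight into CSO, and at which ages.
`dbmtransit` is for epidemiologists and biostatisticians analysing
multi-round cohort panels (anthropometry plus sociodemographics) who want
those dynamics as a fitted model.

## The model

Each subject-round is classified into one of four nutritional states from
WHO-style z-score cutoffs:

- **stunted**: height-for-age z-score HAZ < −2 SD;
- **overweight**: weight-for-height z > 2 SD (under 5 y), BMI-for-age
  z > 1 SD (5–19 y), or BMI > 25 kg/m² (over 19 y);
- **cso**: both criteria at once; **normal**: neither.

State sequences are modelled as a discrete-time first-order Markov chain
with time-inhomogeneous dynamics: a distinct 4×4 transition matrix P(t)
for every between-round interval. With fully observed states the MLE is
closed form, `P_ij(t) = n_ij(t) / n_i(t)`, with plug-in SEs
`sqrt(P_ij (1−P_ij) / n_i)`; marginal state distributions follow by
forward propagation `π(t+1) = π(t) P(t)`.

Covariate effects on transitions are estimated with three binary
two-state models (stunted/not, overweight/not, CSO/not; CSO counts as
stunted in the first and as overweight in the second). For each direction
(into and out of the state) the transition probability follows a logit
parameterization,

    logit P(in state at t+1 | origin, x_t) = α(t) + β' x_t,

with interval-specific intercepts and covariate effects shared across
intervals, fitted by damped Newton–Raphson on the Bernoulli likelihood.
`exp(β)` is the odds ratio of transitioning versus remaining, reported
with 95% Wald intervals. Covariate selection support includes univariate
baseline screening and forward stepwise AIC.

A synthetic cohort generator with known truth (states, logit-scale
covariate effects, state-consistent anthropometry, monotone attrition)
makes the whole pipeline testable by parameter recovery without any
external data.

## Worked example

```r
library(dbmtransit)

cfg <- sim_config(n_subjects = 2000, seed = 3)      # ages 1/5/8/12/15
sim <- simulate_cohort(cfg)
panel <- apply_attrition(simulate_anthropometry(sim$panel, cfg), cfg)

panel <- classify_panel(panel)                       # add states
cc <- complete_case_filter(panel)                    # listwise deletion
cc$log
#> Complete-case filter: 1792 of 2000 subjects retained (89.6%)
#>   excluded, missing round: 208

fit <- markov_fit(cc$panel)
round(unclass(fit$marginals), 3)
#>         normal stunted overweight   cso
#> round_1  0.732   0.232      0.027 0.009
#> round_2  0.621   0.303      0.057 0.019
#> round_3  0.644   0.252      0.083 0.021
#> round_4  0.679   0.161      0.134 0.026
#> round_5  0.702   0.084      0.190 0.025

adj <- run_adjusted_models(cc$panel)
subset(adj$table, target == "stunting" & term == "wealth_qQ4")
#>      target direction       term   beta    se    or ci_low ci_high ...
#>    stunting      into wealth_qQ4 -0.767 0.138 0.464  0.354   0.609
#>    stunting    out_of wealth_qQ4  0.647 0.142 1.910  1.446   2.522
```

The marginals show stunting peaking at the second round and receding
through adolescence while overweight rises — the generator's default
dynamics. The odds ratios say subjects in the richest wealth quartile
have about half the odds of becoming stunted (OR 0.46) and about twice
the odds of stunting reversal (OR 1.91) relative to the poorest quartile,
recovering the generating effects (−0.90 and +0.60 on the log-odds
scale) within sampling error.

A published baseline table for a real cohort is bundled as a worked
example for the descriptive machinery:

```r
tab <- india_yc_baseline_counts()
tot <- tab[tab$variable == "total", c("normal", "stunted", "overweight", "cso")]
round(100 * tot / sum(tot), 1)
#>   normal stunted overweight cso
#>     74.5    25.1        0.2 0.2
baseline_counts_tests(tab)   # chi-squared by state: wealth p < 0.001, ...
```

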