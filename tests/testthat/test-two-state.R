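test_that("two-state collapse codes origins, destinations and covariates", {
  st <- matrix(c("stunted", "stunted", "normal", "normal", "normal"), 1)
  panel <- fixture_panel(1, states = st)
  tsp <- build_two_state_panel(panel, "stunting")
  expect_equal(tsp$origin, c(1L, 1L, 0L, 0L))
  expect_equal(tsp$dest, c(1L, 0L, 0L, 0L))
  expect_equal(tsp$interval, 1:4)

  all_norm <- fixture_panel(3, states = matrix("normal", 3, 5))
  tsp0 <- build_two_state_panel(all_norm, "stunting")
  expect_true(all(tsp0$origin == 0) && all(tsp0$dest == 0))

  # cso counts as stunted in the stunting model, overweight in the other
  st2 <- matrix(c("cso", "cso", "cso", "cso", "cso"), 1)
  p2 <- fixture_panel(1, states = st2)
  expect_true(all(build_two_state_panel(p2, "stunting")$origin == 1))
  expect_true(all(build_two_state_panel(p2, "overweight")$origin == 1))
  expect_true(all(build_two_state_panel(p2, "cso")$origin == 1))
})

test_that("covariates attach from the origin round of each interval", {
  panel <- fixture_panel(2, seed = 3)
  panel$wealth_q <- factor(
    ifelse(panel$round <= 2, "Q1", "Q4"), levels = paste0("Q", 1:4))
  tsp <- build_two_state_panel(panel, "stunting")
  expect_equal(as.character(tsp$wealth_q[tsp$interval == 2]), c("Q1", "Q1"))
  expect_equal(as.character(tsp$wealth_q[tsp$interval == 3]), c("Q4", "Q4"))
})

test_that("intercept-only logistic MLE has its closed form", {
  # 20 events among 100 at risk in a single interval
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(1, 0), c(20, 80))
  fit <- logit_newton(X, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), qlogis(0.2), tolerance = 1e-8)
  expect_equal(unname(fit$coef), log(0.25), tolerance = 1e-8)
})

test_that("Newton engine agrees with glm to high precision", {
  set.seed(5)
  n <- 400
  df <- data.frame(x1 = rnorm(n), x2 = factor(sample(letters[1:3], n, TRUE)))
  eta <- -0.5 + 0.8 * df$x1 + c(a = 0, b = 0.5, c = -0.7)[df$x2]
  df$y <- rbinom(n, 1, plogis(eta))
  X <- model.matrix(~ x1 + x2, df)
  mine <- logit_newton(X, df$y)
  ref <- glm(y ~ x1 + x2, binomial, df, control = glm.control(epsilon = 1e-12))
  expect_true(mine$converged)
  expect_lt(max(abs(mine$coef - coef(ref))), 1e-6)
  expect_lt(max(abs(mine$se - summary(ref)$coefficients[, 2])), 1e-6)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_lt(mine$score_max, 1e-8)
})

test_that("separation and degenerate designs are flagged, not reported", {
  # perfectly separating covariate
  X <- cbind(1, c(rep(0, 20), rep(1, 20)))
  colnames(X) <- c("(Intercept)", "x")
  y <- c(rep(0, 20), rep(1, 20))
  fit <- logit_newton(X, y)
  expect_true(fit$separation || !fit$converged)
  # constant covariate -> singular information
  X2 <- cbind(1, 0); colnames(X2) <- c("(Intercept)", "x")
  fit2 <- logit_newton(X2, rep(c(0, 1), 10))
  expect_true(fit2$singular || fit2$separation)
})

test_that("intercept-only transition fits reproduce empirical interval rates", {
  panel <- fixture_panel(60, seed = 9)
  tsp <- build_two_state_panel(panel, "stunting")
  fit <- fit_transition_logit(tsp, character(0))
  for (d in c("entry", "exit")) {
    f <- fit$directions[[d]]
    expect_true(f$estimable)
    rows <- tsp[tsp$origin == (d == "exit"), ]
    y <- if (d == "entry") rows$dest else 1L - rows$dest
    emp <- tapply(y, rows$interval, mean)
    pred <- predict(fit, data.frame(interval = as.integer(names(emp))),
                    direction = d)
    expect_equal(unname(pred), as.numeric(emp), tolerance = 1e-8)
  }
})

test_that("directions with too few events are non-estimable with a reason", {
  panel <- fixture_panel(50, seed = 14,
                         states = matrix("normal", 50, 5))
  # three cso spells -> three exits at most
  panel$state[panel$subject_id <= 3 & panel$round == 2] <- "cso"
  tsp <- build_two_state_panel(panel, "cso")
  fit <- fit_transition_logit(tsp, character(0))
  expect_false(fit$directions$exit$estimable)
  expect_match(fit$directions$exit$reason, "insufficient events")
  tab <- odds_ratio_table(fit)
  out_row <- tab[tab$direction == "out_of", ]
  expect_false(out_row$estimable)
  expect_true(is.na(out_row$or))
})

test_that("odds-ratio table exponentiates with 95% Wald intervals", {
  z <- qnorm(0.975)
  fit <- structure(list(
    target = "stunting", covariates = "x", interval_levels = 1L,
    directions = list(
      entry = list(estimable = TRUE, reason = "",
                   coef = c("(Intercept)" = -1, x = 0),
                   se = c("(Intercept)" = 0.2, x = 0.1),
                   loglik = -10, k = 2, aic = 24, n_obs = 50, n_events = 10),
      exit = list(estimable = TRUE, reason = "",
                  coef = c("(Intercept)" = -1, x = 0.6931),
                  se = c("(Intercept)" = 0.2, x = 0.1),
                  loglik = -10, k = 2, aic = 24, n_obs = 50, n_events = 10))),
    class = "two_state_fit")
  tab <- odds_ratio_table(fit)
  into <- tab[tab$direction == "into", ]
  expect_equal(into$or, 1)
  expect_equal(into$ci_low, exp(-z * 0.1), tolerance = 1e-6)
  expect_equal(into$ci_high, exp(z * 0.1), tolerance = 1e-6)
  out <- tab[tab$direction == "out_of", ]
  expect_equal(out$or, 2, tolerance = 1e-3)
  expect_equal(out$ci_low, exp(0.6931 - z * 0.1), tolerance = 1e-6)
  # monotone in beta for fixed se
  expect_true(out$or > into$or && out$ci_low > into$ci_low &&
                out$ci_high > into$ci_high)
})

test_that("recoding a binary reference level flips the sign exactly", {
  cfg <- quick_config(n = 1500, seed = 23,
                      effects = default_covariate_effects())
  sim <- simulate_cohort(cfg)
  tsp <- build_two_state_panel(sim$panel, "stunting", "residence")
  fit1 <- fit_transition_logit(tsp, "residence")
  tsp2 <- tsp
  tsp2$residence <- factor(as.character(tsp2$residence),
                           levels = c("rural", "urban"))
  fit2 <- fit_transition_logit(tsp2, "residence")
  b1 <- coef(fit1, "entry")[["residencerural"]]
  b2 <- coef(fit2, "entry")[["residenceurban"]]
  expect_equal(b1, -b2, tolerance = 1e-6)
  or1 <- odds_ratio_table(fit1); or2 <- odds_ratio_table(fit2)
  expect_equal(or1$or[or1$direction == "into"],
               1 / or2$or[or2$direction == "into"], tolerance = 1e-6)
})

test_that("null covariate effects give calibrated Wald z-scores", {
  # beta-hat within 3 SEs of zero in nearly all replicates
  n_ok <- 0; n_tot <- 0
  for (s in 1:25) {
    sim <- simulate_cohort(quick_config(n = 1200, seed = 500 + s))
    tsp <- build_two_state_panel(sim$panel, "stunting", "residence")
    fit <- fit_transition_logit(tsp, "residence")
    for (d in c("entry", "exit")) {
      f <- fit$directions[[d]]
      if (!f$estimable) next
      zval <- abs(f$coef[["residencerural"]] / f$se[["residencerural"]])
      n_ok <- n_ok + (zval < 3)
      n_tot <- n_tot + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.93)
})

test_that("run_adjusted_models orchestrates all targets with shared contracts", {
  cfg <- quick_config(n = 2500, seed = 29, effects = default_covariate_effects())
  sim <- simulate_cohort(cfg)
  res <- run_adjusted_models(sim$panel)
  expect_named(res$fits, c("stunting", "overweight", "cso"))
  expect_true(all(c("target", "direction", "or", "estimable") %in%
                    names(res$table)))
  # wealth gradient on stunting entry points the generated way (protective)
  b <- res$table[res$table$target == "stunting" & res$table$direction == "into" &
                   res$table$term == "wealth_qQ4", ]
  expect_lt(b$or, 1)
  # unseen covariate level at prediction time is an error
  fit <- res$fits$stunting
  expect_error(predict(fit, data.frame(interval = 1, sex = "other",
                                       wealth_q = "Q1", residence = "urban",
                                       hh_size = "le5"), "entry"),
               "unseen")
})
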