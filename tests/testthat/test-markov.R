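test_that("transition counts match hand tallies", {
  st <- matrix(c("normal", "stunted", "stunted", "normal", "normal"), 1)
  panel <- fixture_panel(1, states = st)
  counts <- count_transitions(panel)
  expect_equal(counts$counts[[1]]["normal", "stunted"], 1L)
  expect_equal(counts$counts[[2]]["stunted", "stunted"], 1L)
  expect_equal(counts$counts[[3]]["stunted", "normal"], 1L)
  expect_equal(counts$counts[[4]]["normal", "normal"], 1L)
  expect_equal(sum(sapply(counts$counts, sum)), 4L)
})

test_that("constant-state subjects produce purely diagonal counts", {
  st <- matrix(rep(c("normal", "stunted", "overweight"), each = 5), 3, 5,
               byrow = TRUE)
  panel <- fixture_panel(3, states = st)
  counts <- count_transitions(panel)
  for (m in counts$counts) expect_equal(sum(m) - sum(diag(m)), 0L)
})

test_that("counts equal an independent nested-loop tally on a fixture", {
  panel <- fixture_panel(20, seed = 2)
  counts <- count_transitions(panel)
  oracle <- oracle_transition_counts(panel)
  for (t in 1:4) expect_equal(counts$counts[[t]], oracle[[t]])
})

test_that("gappy panels are rejected with a pointer to preparation", {
  panel <- fixture_panel(3)
  panel <- panel[!(panel$subject_id == 1 & panel$round == 3), ]
  expect_error(count_transitions(panel), "complete_case_filter")
})

test_that("MLE matrices are count ratios with plug-in SEs", {
  states <- nutritional_states()
  m <- matrix(0L, 4, 4, dimnames = list(states, states))
  m["normal", ] <- c(8L, 2L, 0L, 0L)
  m["stunted", ] <- c(5L, 5L, 0L, 0L)
  counts <- structure(list(counts = list(interval_1 = m), rounds = 1:2,
                           n_subjects = 20L), class = "transition_counts")
  tms <- mle_transitions(counts)
  f <- tms$intervals[[1]]
  expect_equal(unname(f$P["normal", ]), c(0.8, 0.2, 0, 0))
  expect_equal(f$se["normal", "normal"], sqrt(0.8 * 0.2 / 10), tolerance = 1e-12)
  # unoccupied origin rows are undefined and flagged, not zero
  expect_true(all(is.na(f$P["overweight", ])))
  expect_setequal(f$undefined_rows, c("overweight", "cso"))
  # defined rows are stochastic
  expect_equal(sum(f$P["normal", ]), 1, tolerance = 1e-12)
})

test_that("estimates sit within Monte-Carlo error of generating matrices", {
  # 3-SE entrywise bound on well-populated rows across several seeds
  n_bad <- 0; n_tot <- 0
  for (s in 1:5) {
    cfg <- quick_config(n = 20000, seed = 300 + s)
    sim <- simulate_cohort(cfg)
    tms <- mle_transitions(count_transitions(sim$panel))
    for (t in seq_along(tms$intervals)) {
      f <- tms$intervals[[t]]
      P_true <- cfg$transition_matrices[[t]]
      for (i in which(f$n_from > 200)) {
        se <- sqrt(P_true[i, ] * (1 - P_true[i, ]) / f$n_from[i])
        dev <- abs(f$P[i, ] - P_true[i, ])
        n_bad <- n_bad + sum(dev > 3 * se + 1e-12)
        n_tot <- n_tot + 4
      }
    }
  }
  expect_lt(n_bad / n_tot, 0.01 + 3 * sqrt(0.003 / n_tot))
})

test_that("marginal propagation: identity chain, one-step product, errors", {
  states <- nutritional_states()
  I4 <- diag(4); dimnames(I4) <- list(states, states)
  counts <- structure(list(counts = list(a = I4 * 10L, b = I4 * 10L),
                           rounds = 1:3, n_subjects = 10L),
                      class = "transition_counts")
  tms <- mle_transitions(counts)
  init <- c(0.4, 0.3, 0.2, 0.1)
  traj <- marginal_trajectory(init, tms)
  expect_equal(unname(unclass(traj)[3, ]), init)

  m <- I4 * 10L; m["normal", ] <- c(5L, 5L, 0L, 0L)
  counts2 <- structure(list(counts = list(a = m), rounds = 1:2,
                            n_subjects = 10L), class = "transition_counts")
  traj2 <- marginal_trajectory(c(1, 0, 0, 0), mle_transitions(counts2))
  expect_equal(unname(unclass(traj2)[2, ]), c(0.5, 0.5, 0, 0))

  # undefined row reachable with positive probability -> error
  m3 <- I4 * 10L; m3["cso", ] <- 0L
  counts3 <- structure(list(counts = list(a = m3), rounds = 1:2,
                            n_subjects = 10L), class = "transition_counts")
  expect_error(marginal_trajectory(c(0.25, 0.25, 0.25, 0.25),
                                   mle_transitions(counts3)),
               "undefined")
  # but harmless when that state has zero mass
  expect_silent(marginal_trajectory(c(0.5, 0.3, 0.2, 0),
                                    mle_transitions(counts3)))
})

test_that("saturated-model identity: propagated marginals = empirical freqs", {
  for (s in c(4, 44)) {
    panel <- fixture_panel(30, seed = s)
    fit <- markov_fit(panel)
    expect_equal(unname(unclass(fit$marginals)), oracle_round_freqs(panel),
                 tolerance = 1e-12)
  }
})

test_that("pooled homogeneous fit is the count-weighted interval average", {
  panel <- fixture_panel(25, seed = 6)
  counts <- count_transitions(panel)
  pooled <- pool_transitions(counts)$intervals[[1]]
  tms <- mle_transitions(counts)
  states <- nutritional_states()
  for (i in states) {
    num <- rep(0, 4); den <- 0
    for (t in seq_along(tms$intervals)) {
      f <- tms$intervals[[t]]
      if (f$n_from[i] > 0) {
        num <- num + f$n_from[i] * f$P[i, ]
        den <- den + f$n_from[i]
      }
    }
    if (den > 0) expect_equal(unname(pooled$P[i, ]), unname(num / den),
                              tolerance = 1e-12)
  }
})

test_that("stratified fits recover stratum-specific dynamics", {
  panel <- fixture_panel(40, seed = 10)
  single <- stratified_markov(within(panel, sex[] <- "male"), "sex")
  whole <- markov_fit(within(panel, sex[] <- "male"))
  expect_equal(coef(single$male), coef(whole))

  # sex-specific generating matrices: each stratum recovers its own truth
  mk <- function(a) product_transition_matrix(a, 0.3, 0.05, 0.4)
  cfg_m <- quick_config(n = 6000, seed = 71,
                        transition_matrices = rep(list(mk(0.30)), 4))
  cfg_f <- quick_config(n = 6000, seed = 72,
                        transition_matrices = rep(list(mk(0.05)), 4))
  sim_m <- simulate_cohort(cfg_m)$panel
  sim_f <- simulate_cohort(cfg_f)$panel
  sim_m$sex <- factor("male", levels = c("male", "female"))
  sim_f$sex <- factor("female", levels = c("male", "female"))
  sim_f$subject_id <- sim_f$subject_id + 10000
  both <- rbind(sim_m, sim_f)
  fits <- stratified_markov(both, "sex")
  pm <- coef(fits$male)[[1]]["normal", "stunted"]
  pf <- coef(fits$female)[[1]]["normal", "stunted"]
  true_m <- mk(0.30)["normal", "stunted"]
  true_f <- mk(0.05)["normal", "stunted"]
  expect_lt(abs(pm - true_m), 3 * sqrt(true_m * (1 - true_m) / 4000))
  expect_lt(abs(pf - true_f), 3 * sqrt(true_f * (1 - true_f) / 4000))
  expect_error(stratified_markov(both, "round"), "time-constant")
})

test_that("tidy transition export carries every interval cell", {
  panel <- fixture_panel(15, seed = 20)
  tms <- mle_transitions(count_transitions(panel))
  tab <- transitions_as_table(tms, "YC")
  expect_equal(nrow(tab), 4 * 16)
  expect_named(tab, c("cohort", "interval", "from_state", "to_state",
                      "n_from", "p", "se"))
  row <- tab[tab$interval == tab$interval[1] & tab$from_state == "normal" &
               tab$to_state == "stunted", ]
  expect_equal(row$p, tms$intervals[[1]]$P["normal", "stunted"])
})
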