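# Shared fixtures and independent oracles. Oracles are deliberately
# naive (nested loops, direct formulas) and never call the code paths
# they check.

quick_config <- function(n = 200, seed = 1, effects = NULL,
                         dropout = 0, missing = 0, ...) {
  sim_config(n_subjects = n, seed = seed, covariate_effects = effects,
             dropout_prob = dropout, missing_prob = missing, ...)
}

# deterministic 20-subject complete-case panel with hand-settable states
fixture_panel <- function(n_subjects = 20, n_rounds = 5, seed = 42,
                          states = NULL) {
  set.seed(seed)
  levels4 <- nutritional_states()
  if (is.null(states)) {
    states <- matrix(sample(levels4, n_subjects * n_rounds, replace = TRUE,
                            prob = c(0.6, 0.25, 0.1, 0.05)),
                     n_subjects, n_rounds)
  }
  panel <- expand.grid(round = seq_len(n_rounds),
                       subject_id = seq_len(n_subjects))
  panel <- panel[, c("subject_id", "round")]
  panel$age_years <- c(1, 5, 8, 12, 15)[panel$round]
  panel$state <- factor(states[cbind(panel$subject_id, panel$round)],
                        levels = levels4)
  panel$cohort <- "YC"
  set.seed(seed + 1)
  subj_cov <- data.frame(
    subject_id = seq_len(n_subjects),
    sex = factor(sample(c("male", "female"), n_subjects, TRUE),
                 levels = c("male", "female")),
    wealth_q = factor(sample(paste0("Q", 1:4), n_subjects, TRUE),
                      levels = paste0("Q", 1:4)),
    residence = factor(sample(c("urban", "rural"), n_subjects, TRUE),
                       levels = c("urban", "rural")),
    hh_size = factor(sample(c("le5", "gt5"), n_subjects, TRUE),
                     levels = c("le5", "gt5")),
    mat_edu = factor(sample(c("le6y", "gt6y"), n_subjects, TRUE),
                     levels = c("le6y", "gt6y"))
  )
  merge(panel, subj_cov, by = "subject_id")
}

# brute-force transition tally: nested loops over subjects and intervals
oracle_transition_counts <- function(panel) {
  states <- nutritional_states()
  rounds <- sort(unique(panel$round))
  out <- lapply(seq_len(length(rounds) - 1), function(t) {
    m <- matrix(0L, 4, 4, dimnames = list(states, states))
    m
  })
  for (id in unique(panel$subject_id)) {
    d <- panel[panel$subject_id == id, ]
    d <- d[order(d$round), ]
    for (t in seq_len(nrow(d) - 1)) {
      i <- as.character(d$state[t]); j <- as.character(d$state[t + 1])
      out[[t]][i, j] <- out[[t]][i, j] + 1L
    }
  }
  out
}

# direct-sum Pearson chi-squared statistic
oracle_chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# empirical round-wise state frequencies
oracle_round_freqs <- function(panel) {
  t(sapply(sort(unique(panel$round)), function(r) {
    s <- panel$state[panel$round == r]
    as.numeric(table(factor(s, levels = nutritional_states()))) / length(s)
  }))
}
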