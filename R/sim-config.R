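#' Build a four-state transition matrix from two independent binary splits
#'
#' Constructs a 4x4 row-stochastic transition matrix over
#' (normal, stunted, overweight, cso) as the product of two independent
#' binary chains: a stunting-status chain and an overweight-status chain.
#' Conditional on the current state, the next stunting status and the next
#' overweight status are drawn independently; e.g. the probability that a
#' currently normal child becomes cso is \code{stunt_entry * ow_entry}.
#'
#' Under this construction the probability of entering (or leaving) the
#' stunted group \{stunted, cso\} is identical from every origin outside
#' (inside) the group, and likewise for the overweight group — exactly the
#' structure assumed by the two-state logit transition models, which makes
#' covariate-effect recovery on simulated cohorts well-specified rather
#' than approximate.
#'
#' @param stunt_entry Probability a non-stunted child becomes stunted over
#'   the interval.
#' @param stunt_exit Probability a stunted child reverts to non-stunted.
#' @param ow_entry Probability a non-overweight child becomes overweight.
#' @param ow_exit Probability an overweight child reverts.
#' @return 4x4 row-stochastic matrix with dimnames over the state labels.
#' @export
#' @examples
#' P <- product_transition_matrix(0.2, 0.3, 0.05, 0.4)
#' rowSums(P)  # all 1
product_transition_matrix <- function(stunt_entry, stunt_exit, ow_entry, ow_exit) {
  p <- c(stunt_entry, stunt_exit, ow_entry, ow_exit)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("split probabilities must lie in [0, 1]")
  }
  states <- nutritional_states()
  # next stunting-status probability of being stunted, given current status
  s_next <- function(stunted_now) if (stunted_now) 1 - stunt_exit else stunt_entry
  o_next <- function(ow_now) if (ow_now) 1 - ow_exit else ow_entry
  is_s <- c(normal = FALSE, stunted = TRUE, overweight = FALSE, cso = TRUE)
  is_o <- c(normal = FALSE, stunted = FALSE, overweight = TRUE, cso = TRUE)
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  for (from in states) {
    ps <- s_next(is_s[[from]])
    po <- o_next(is_o[[from]])
    P[from, "normal"]     <- (1 - ps) * (1 - po)
    P[from, "stunted"]    <- ps * (1 - po)
    P[from, "overweight"] <- (1 - ps) * po
    P[from, "cso"]        <- ps * po
  }
  P
}

#' Default covariate effects on transitions
#'
#' The generating covariate effects used by \code{\link{sim_config}} when
#' none are supplied. Effects are log-odds shifts applied to the logit of
#' the probability of entering or leaving a target state group, mirroring
#' the parameterization of \code{\link{fit_transition_logit}}. The defaults
#' emulate gradients typical of cohorts in countries undergoing nutrition
#' transition: wealth protects against stunting entry and promotes both
#' stunting reversal and overweight entry; rural residence raises stunting
#' entry and lowers overweight entry.
#'
#' @return Data frame with columns \code{target}, \code{direction}
#'   (\code{"entry"} or \code{"exit"}), \code{covariate}, \code{level},
#'   \code{beta} (log-odds shift per indicator, or per unit for numeric
#'   covariates with \code{level = NA}).
#' @export
default_covariate_effects <- function() {
  data.frame(
    target = c(rep("stunting", 6), rep("overweight", 5)),
    direction = c(rep("entry", 4), "exit", "exit",
                  rep("entry", 4), "exit"),
    covariate = c("wealth_q", "wealth_q", "wealth_q", "residence",
                  "wealth_q", "wealth_q",
                  "wealth_q", "wealth_q", "wealth_q", "residence",
                  "residence"),
    level = c("Q2", "Q3", "Q4", "rural", "Q3", "Q4",
              "Q2", "Q3", "Q4", "rural", "rural"),
    beta = c(-0.30, -0.55, -0.90, 0.50, 0.30, 0.60,
             0.30, 0.60, 1.00, -0.60, 0.20),
    stringsAsFactors = FALSE
  )
}

#' Default covariate marginal distributions and dynamics
#'
#' Marginals for the sociodemographic covariates of a simulated cohort,
#' plus the stay probability of the sticky Markov process that moves the
#' time-varying covariates (wealth quartile, residence, household size)
#' between rounds. Sex and maternal education are fixed at baseline.
#'
#' @return Named list of level-probability vectors plus \code{stay_prob}.
#' @export
default_covariate_specs <- function() {
  list(
    sex       = c(male = 0.5, female = 0.5),
    wealth_q  = c(Q1 = 0.25, Q2 = 0.25, Q3 = 0.25, Q4 = 0.25),
    residence = c(urban = 0.3, rural = 0.7),
    hh_size   = c(le5 = 0.6, gt5 = 0.4),
    mat_edu   = c(le6y = 0.7, gt6y = 0.3),
    stay_prob = 0.9
  )
}

#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Bundles and validates everything the simulator needs: cohort shape
#' (subjects, rounds, ages), baseline state distribution, per-interval
#' 4x4 transition matrices at the reference covariate profile, covariate
#' effects on the logit scale, covariate marginals and dynamics, and the
#' attrition mechanism.
#'
#' Defaults emulate a younger five-round cohort measured at ages
#' 1, 5, 8, 12, 15 with baseline stunting around 25\% and overweight
#' around 3\%, stunting onset concentrated in the first interval and
#' reversal rising through adolescence, overweight onset rising with age,
#' per-round dropout of 2.5\% and sparse field-level missingness —
#' the structure of multi-round child cohort studies in low- and
#' middle-income countries.
#'
#' @param n_subjects Number of subjects.
#' @param round_ages Strictly increasing ages in years, one per round.
#' @param initial_state_probs Length-4 probability vector over
#'   (normal, stunted, overweight, cso); must sum to 1.
#' @param transition_matrices List of \code{length(round_ages) - 1}
#'   row-stochastic 4x4 matrices (dynamics at the reference covariate
#'   profile).
#' @param covariate_effects Data frame as in
#'   \code{\link{default_covariate_effects}}, or \code{NULL} for no effects.
#' @param covariate_specs List as in \code{\link{default_covariate_specs}}.
#' @param dropout_prob Per-round probability (rounds 2 onward) that a
#'   subject drops out; dropout is monotone (no return).
#' @param missing_prob Per-field probability that an anthropometric value
#'   is missing in an otherwise observed round.
#' @param cohort Cohort label stored in the panel (e.g. \code{"YC"}).
#' @param seed Integer seed; every stochastic draw of the simulator flows
#'   from this single seed.
#' @return Object of class \code{"sim_config"}.
#' @seealso \code{\link{simulate_cohort}}
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 100, seed = 1)
#' sapply(cfg$transition_matrices, function(P) max(abs(rowSums(P) - 1)))
sim_config <- function(n_subjects,
                       round_ages = c(1, 5, 8, 12, 15),
                       initial_state_probs = NULL,
                       transition_matrices = NULL,
                       covariate_effects = default_covariate_effects(),
                       covariate_specs = default_covariate_specs(),
                       dropout_prob = 0.025,
                       missing_prob = 0.005,
                       cohort = "YC",
                       seed = 1L) {
  if (length(n_subjects) != 1 || !is.finite(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be a positive integer")
  }
  n_subjects <- as.integer(n_subjects)
  if (any(diff(round_ages) <= 0)) stop("round_ages must be strictly increasing")
  n_rounds <- length(round_ages)
  if (n_rounds < 2) stop("need at least two rounds")

  if (is.null(initial_state_probs)) {
    # independent baseline splits: 25% stunted, 3% overweight
    initial_state_probs <- c(0.75 * 0.97, 0.25 * 0.97, 0.75 * 0.03, 0.25 * 0.03)
  }
  if (length(initial_state_probs) != 4 || any(initial_state_probs < 0) ||
      abs(sum(initial_state_probs) - 1) > 1e-8) {
    stop("initial_state_probs must be 4 non-negative probabilities summing to 1")
  }
  names(initial_state_probs) <- nutritional_states()

  if (is.null(transition_matrices)) {
    splits <- default_interval_splits(n_rounds - 1)
    transition_matrices <- lapply(seq_len(n_rounds - 1), function(t) {
      product_transition_matrix(splits$stunt_entry[t], splits$stunt_exit[t],
                                splits$ow_entry[t], splits$ow_exit[t])
    })
  }
  if (length(transition_matrices) != n_rounds - 1) {
    stop("need one transition matrix per between-round interval")
  }
  for (P in transition_matrices) {
    if (!is.matrix(P) || !all(dim(P) == 4)) stop("transition matrices must be 4x4")
    if (any(P < 0)) stop("transition probabilities must be non-negative")
    if (any(abs(rowSums(P) - 1) > 1e-12)) {
      stop("each transition matrix row must sum to 1 (within 1e-12)")
    }
  }
  transition_matrices <- lapply(transition_matrices, function(P) {
    dimnames(P) <- list(nutritional_states(), nutritional_states())
    P
  })

  if (!is.null(covariate_effects)) {
    stopifnot(all(c("target", "direction", "covariate", "beta") %in%
                    names(covariate_effects)))
    if (!all(covariate_effects$target %in% names(.target_groups))) {
      stop("unknown target in covariate_effects")
    }
    if (!all(covariate_effects$direction %in% c("entry", "exit"))) {
      stop("covariate_effects$direction must be 'entry' or 'exit'")
    }
  }
  if (length(dropout_prob) == 1) dropout_prob <- rep(dropout_prob, n_rounds - 1)
  if (length(dropout_prob) != n_rounds - 1 || any(dropout_prob < 0) ||
      any(dropout_prob > 1)) {
    stop("dropout_prob must be one probability, or one per interval, in [0, 1]")
  }
  if (missing_prob < 0 || missing_prob > 1) stop("missing_prob must be in [0, 1]")

  structure(list(
    n_subjects = n_subjects,
    n_rounds = n_rounds,
    round_ages = round_ages,
    initial_state_probs = initial_state_probs,
    transition_matrices = transition_matrices,
    covariate_effects = covariate_effects,
    covariate_specs = covariate_specs,
    dropout_prob = dropout_prob,
    missing_prob = missing_prob,
    cohort = cohort,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# per-interval binary-split probabilities behind the default matrices:
# stunting onset front-loaded in early childhood, reversal rising with
# age; overweight onset rising with age, reversal falling.
default_interval_splits <- function(n_intervals) {
  stunt_entry <- c(0.22, 0.09, 0.05, 0.04)
  stunt_exit  <- c(0.25, 0.30, 0.40, 0.50)
  ow_entry    <- c(0.05, 0.05, 0.09, 0.10)
  ow_exit     <- c(0.45, 0.40, 0.35, 0.30)
  idx <- pmin(seq_len(n_intervals), 4L)
  list(stunt_entry = stunt_entry[idx], stunt_exit = stunt_exit[idx],
       ow_entry = ow_entry[idx], ow_exit = ow_exit[idx])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, rounds: %d (ages %s), cohort: %s, seed: %d\n",
              x$n_subjects, x$n_rounds,
              paste(x$round_ages, collapse = ", "), x$cohort, x$seed))
  cat(sprintf("  baseline states: %s\n",
              paste(sprintf("%s %.3f", names(x$initial_state_probs),
                            x$initial_state_probs), collapse = ", ")))
  n_eff <- if (is.null(x$covariate_effects)) 0 else nrow(x$covariate_effects)
  cat(sprintf("  covariate effects: %d, dropout/round: %s, field missingness: %.3f\n",
              n_eff, paste(format(x$dropout_prob), collapse = "/"),
              x$missing_prob))
  invisible(x)
}
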