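#' Tally observed state-to-state transitions per interval
#'
#' Sufficient statistics of the discrete-time first-order four-state
#' chain: for each between-round interval t, the 4x4 matrix of subjects in
#' state i at round t and state j at round t+1. Requires a complete-case
#' panel — subjects with missing rounds or states must be removed first
#' (see \code{\link{complete_case_filter}}).
#'
#' @param panel Complete-case panel with \code{subject_id}, \code{round},
#'   \code{state}.
#' @return Class \code{"transition_counts"}: list of per-interval integer
#'   matrices, plus round count and subject count.
#' @export
count_transitions <- function(panel) {
  rounds <- sort(unique(panel$round))
  R <- length(rounds)
  if (R < 2) stop("need at least two rounds")
  panel <- panel[order(panel$subject_id, panel$round), , drop = FALSE]
  per_subj <- table(panel$subject_id)
  if (any(per_subj != R)) {
    stop("panel has subjects with missing rounds; run complete_case_filter first")
  }
  if (any(is.na(panel$state))) {
    stop("panel has missing states; run complete_case_filter first")
  }
  st <- matrix(as.character(panel$state), ncol = R, byrow = TRUE)
  states <- nutritional_states()
  counts <- lapply(seq_len(R - 1), function(t) {
    tab <- table(factor(st[, t], levels = states),
                 factor(st[, t + 1], levels = states))
    m <- matrix(as.integer(tab), 4, 4, dimnames = list(states, states))
    m
  })
  names(counts) <- paste0("interval_", seq_len(R - 1))
  structure(list(counts = counts, rounds = rounds,
                 n_subjects = length(per_subj)),
            class = "transition_counts")
}

#' Per-interval MLE transition matrices with standard errors
#'
#' Closed-form maximum likelihood for the saturated time-inhomogeneous
#' chain with fully observed states: \code{P_ij(t) = n_ij(t) / n_i(t)},
#' with plug-in multinomial standard errors
#' \code{sqrt(P_ij (1 - P_ij) / n_i)}. Origin states unoccupied at a
#' round yield an undefined (all-\code{NA}) row, flagged rather than
#' filled with zeros.
#'
#' @param counts A \code{\link{count_transitions}} result.
#' @param interval_labels Optional labels (e.g. \code{"1-5 years"}), one
#'   per interval.
#' @return Class \code{"transition_matrix_set"}: per interval, \code{P},
#'   \code{se}, \code{n_from} (row totals) and \code{undefined_rows}.
#' @export
mle_transitions <- function(counts, interval_labels = NULL) {
  stopifnot(inherits(counts, "transition_counts"))
  fits <- lapply(counts$counts, function(m) {
    n_i <- rowSums(m)
    P <- m / ifelse(n_i > 0, n_i, NA_real_)
    se <- sqrt(P * (1 - P) / n_i)
    undef <- n_i == 0
    P[undef, ] <- NA_real_
    se[undef, ] <- NA_real_
    list(P = P, se = se, n_from = n_i, undefined_rows = names(n_i)[undef])
  })
  if (is.null(interval_labels)) {
    r <- counts$rounds
    interval_labels <- paste(r[-length(r)], r[-1], sep = "-")
  }
  structure(list(intervals = fits, interval_labels = interval_labels,
                 rounds = counts$rounds, n_subjects = counts$n_subjects),
            class = "transition_matrix_set")
}

#' @export
print.transition_matrix_set <- function(x, digits = 3, ...) {
  cat(sprintf("Time-inhomogeneous transition matrices (%d intervals, %d subjects)\n",
              length(x$intervals), x$n_subjects))
  for (i in seq_along(x$intervals)) {
    cat(sprintf("\nInterval %s (n at origin: %s)\n", x$interval_labels[i],
                paste(x$intervals[[i]]$n_from, collapse = "/")))
    print(round(x$intervals[[i]]$P, digits))
    if (length(x$intervals[[i]]$undefined_rows)) {
      cat("  undefined rows (no subjects at origin):",
          paste(x$intervals[[i]]$undefined_rows, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Propagate an initial state distribution through the fitted chain
#'
#' Computes the marginal state distribution at every round by forward
#' propagation: \code{pi(t+1) = pi(t) \%*\% P(t)}. Undefined transition
#' rows are tolerated only when the propagated probability of occupying
#' that origin state is zero; otherwise the trajectory is not computable
#' and an error is raised.
#'
#' @param initial Length-4 probability vector over the states at round 1
#'   (typically the empirical baseline frequencies).
#' @param tms A \code{\link{mle_transitions}} result.
#' @return Class \code{"marginal_trajectory"}: matrix, rounds x states,
#'   each row summing to 1.
#' @export
marginal_trajectory <- function(initial, tms) {
  stopifnot(inherits(tms, "transition_matrix_set"))
  states <- nutritional_states()
  if (length(initial) != 4 || abs(sum(initial) - 1) > 1e-8 || any(initial < 0)) {
    stop("initial must be 4 non-negative probabilities summing to 1")
  }
  R <- length(tms$intervals) + 1
  traj <- matrix(NA_real_, R, 4, dimnames = list(paste0("round_", seq_len(R)),
                                                 states))
  pi_t <- stats::setNames(as.numeric(initial), states)
  traj[1, ] <- pi_t
  for (t in seq_along(tms$intervals)) {
    P <- tms$intervals[[t]]$P
    undef <- !stats::complete.cases(P)
    if (any(undef & pi_t > 0)) {
      stop(sprintf("interval %d: undefined transition row '%s' reachable with positive probability",
                   t, states[undef & pi_t > 0][1]))
    }
    Pz <- P
    Pz[undef, ] <- 0
    pi_t <- as.numeric(pi_t %*% Pz)
    names(pi_t) <- states
    traj[t + 1, ] <- pi_t
  }
  structure(traj, class = c("marginal_trajectory", "matrix"))
}

#' Fit the unadjusted four-state Markov chain to a panel
#'
#' Convenience wrapper tying the pieces together: transition counts,
#' per-interval MLE matrices with SEs, and the marginal state trajectory
#' propagated from the empirical baseline distribution. For the saturated
#' time-inhomogeneous model on complete cases, the propagated marginals
#' coincide exactly with the empirical round-wise state frequencies.
#'
#' @param panel Complete-case classified panel.
#' @param interval_labels Optional interval labels.
#' @return Class \code{"markov_fit"} with components \code{counts},
#'   \code{transitions} (\code{transition_matrix_set}), \code{marginals}
#'   and \code{initial}.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 300, seed = 2))
#' fit <- markov_fit(sim$panel)
#' fit$marginals
markov_fit <- function(panel, interval_labels = NULL) {
  counts <- count_transitions(panel)
  tms <- mle_transitions(counts, interval_labels)
  base <- panel[panel$round == min(panel$round), , drop = FALSE]
  initial <- as.numeric(table(base$state)) / nrow(base)
  structure(list(counts = counts, transitions = tms,
                 marginals = marginal_trajectory(initial, tms),
                 initial = stats::setNames(initial, nutritional_states())),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, digits = 3, ...) {
  cat("Unadjusted four-state Markov chain fit\n")
  cat(sprintf("  %d subjects, %d rounds\n", x$counts$n_subjects,
              length(x$counts$rounds)))
  cat("\nMarginal state distribution by round:\n")
  print(round(unclass(x$marginals), digits))
  cat("\nUse summary() for per-interval transition matrices.\n")
  invisible(x)
}

#' @export
summary.markov_fit <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  print(object$transitions, digits = digits)
  invisible(object)
}

#' @export
coef.markov_fit <- function(object, ...) {
  lapply(object$transitions$intervals, `[[`, "P")
}

#' Plot marginal state trajectories
#'
#' Line plot of the four marginal state probabilities over rounds.
#'
#' @param x A \code{"markov_fit"}.
#' @param ages Optional x-axis ages (default round index).
#' @param ... Passed to \code{matplot}.
#' @export
plot.markov_fit <- function(x, ages = NULL, ...) {
  m <- unclass(x$marginals)
  if (is.null(ages)) ages <- seq_len(nrow(m))
  graphics::matplot(ages, m, type = "b", pch = 16, lty = 1,
                    xlab = "age (years)", ylab = "marginal probability", ...)
  graphics::legend("topright", colnames(m), col = seq_len(4), lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Stratified Markov fits
#'
#' Fits the unadjusted four-state chain independently within each level of
#' a time-constant stratifier (e.g. sex), the standard sensitivity check
#' that growth dynamics do not differ between strata.
#'
#' @param panel Complete-case classified panel.
#' @param stratifier Column name; must be constant within subject.
#' @return Named list of \code{\link{markov_fit}} objects, one per stratum.
#' @export
stratified_markov <- function(panel, stratifier = "sex") {
  v <- panel[[stratifier]]
  if (is.null(v)) stop("stratifier column not found: ", stratifier)
  chk <- tapply(as.character(v), panel$subject_id,
                function(z) length(unique(z)))
  if (any(chk > 1)) stop("stratifier must be time-constant within subject")
  levs <- levels(factor(v))
  out <- lapply(stats::setNames(levs, levs), function(l) {
    sub <- panel[v == l, , drop = FALSE]
    if (nrow(sub) == 0) stop("stratum with zero subjects: ", l)
    markov_fit(sub)
  })
  out
}

#' Pool transition counts across intervals
#'
#' Collapses per-interval counts into a single matrix and fits one
#' time-homogeneous transition matrix — by construction the count-weighted
#' average of the per-interval estimates.
#'
#' @param counts A \code{\link{count_transitions}} result.
#' @return Class \code{"transition_matrix_set"} with a single interval.
#' @export
pool_transitions <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  pooled <- Reduce(`+`, counts$counts)
  c2 <- structure(list(counts = list(pooled = pooled),
                       rounds = range(counts$rounds),
                       n_subjects = counts$n_subjects),
                  class = "transition_counts")
  mle_transitions(c2, interval_labels = "pooled")
}

#' Export transition estimates as a tidy data frame
#'
#' @param tms A \code{\link{mle_transitions}} result.
#' @param cohort Cohort label for the output.
#' @return Data frame: cohort, interval, from_state, to_state, n_from,
#'   p, se.
#' @export
transitions_as_table <- function(tms, cohort = "") {
  stopifnot(inherits(tms, "transition_matrix_set"))
  states <- nutritional_states()
  rows <- lapply(seq_along(tms$intervals), function(t) {
    f <- tms$intervals[[t]]
    expand <- expand.grid(from_state = states, to_state = states,
                          stringsAsFactors = FALSE)
    expand$cohort <- cohort
    expand$interval <- tms$interval_labels[t]
    expand$n_from <- f$n_from[expand$from_state]
    expand$p <- f$P[cbind(expand$from_state, expand$to_state)]
    expand$se <- f$se[cbind(expand$from_state, expand$to_state)]
    expand[, c("cohort", "interval", "from_state", "to_state", "n_from",
               "p", "se")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
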