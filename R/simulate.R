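#' Simulate a longitudinal nutritional-state cohort with known truth
#'
#' Draws a long-format panel of \code{n_subjects} followed over
#' \code{n_rounds} rounds: sociodemographic covariates (sex, wealth
#' quartile, residence, household size, maternal education; the middle
#' three evolve between rounds by a sticky Markov process), a baseline
#' nutritional state from \code{initial_state_probs}, and subsequent states
#' from the per-interval transition matrices modulated on the logit scale
#' by the configured covariate effects — the same parameterization the
#' two-state transition models estimate, so fitted log-odds are directly
#' comparable with the generating ones.
#'
#' Anthropometric columns are initialized to \code{NA}; fill them with
#' \code{\link{simulate_anthropometry}}. Attrition is applied separately by
#' \code{\link{apply_attrition}}. All randomness flows from the single
#' \code{config$seed}, set once at the start of this function; the same
#' config therefore yields a bit-identical panel, and downstream stochastic
#' stages continue the same stream.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{panel} (data frame, one row per subject-round:
#'   subject_id, cohort, round, age_years, state, haz, whz, baz, bmi and
#'   covariates) and \code{truth} (class \code{"sim_truth"}: the config plus
#'   exact conditional transition probabilities via
#'   \code{\link{true_transition_matrix}}).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 50, seed = 7))
#' table(sim$panel$state[sim$panel$round == 1])
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  R <- config$n_rounds
  states <- nutritional_states()

  covs <- simulate_covariates(config)

  state <- matrix(NA_character_, n, R)
  state[, 1] <- sample(states, n, replace = TRUE, prob = config$initial_state_probs)
  for (t in seq_len(R - 1)) {
    x_t <- covs[covs$round == t, , drop = FALSE]
    x_t <- x_t[order(x_t$subject_id), , drop = FALSE]
    eta <- effect_linear_predictor(config$covariate_effects, x_t)
    state[, t + 1] <- draw_next_states(state[, t], config$transition_matrices[[t]],
                                       eta)
  }

  panel <- data.frame(
    subject_id = rep(seq_len(n), times = R),
    cohort = config$cohort,
    round = rep(seq_len(R), each = n),
    age_years = rep(config$round_ages, each = n),
    state = as_state_factor(as.vector(state)),
    haz = NA_real_, whz = NA_real_, baz = NA_real_, bmi = NA_real_,
    stringsAsFactors = FALSE
  )
  covs <- covs[order(covs$round, covs$subject_id), , drop = FALSE]
  for (v in c("sex", "wealth_q", "residence", "hh_size", "mat_edu")) {
    panel[[v]] <- covs[[v]]
  }
  panel <- panel[order(panel$subject_id, panel$round), , drop = FALSE]
  rownames(panel) <- NULL

  truth <- structure(list(config = config), class = "sim_truth")
  list(panel = panel, truth = truth)
}

# baseline covariates from the configured marginals, then sticky Markov
# moves for the time-varying ones (wealth_q, residence, hh_size)
simulate_covariates <- function(config) {
  n <- config$n_subjects
  R <- config$n_rounds
  sp <- config$covariate_specs
  stay <- sp$stay_prob
  draw_level <- function(probs, size) {
    factor(sample(names(probs), size, replace = TRUE, prob = probs),
           levels = names(probs))
  }
  base <- data.frame(
    subject_id = seq_len(n),
    sex = draw_level(sp$sex, n),
    wealth_q = draw_level(sp$wealth_q, n),
    residence = draw_level(sp$residence, n),
    hh_size = draw_level(sp$hh_size, n),
    mat_edu = draw_level(sp$mat_edu, n)
  )
  out <- vector("list", R)
  out[[1]] <- cbind(base, round = 1L)
  cur <- base
  for (t in 2:R) {
    for (v in c("wealth_q", "residence", "hh_size")) {
      levs <- levels(cur[[v]])
      move <- stats::runif(n) > stay
      if (any(move)) {
        # uniformly among the other levels
        new_lev <- vapply(as.character(cur[[v]][move]), function(l) {
          sample(setdiff(levs, l), 1L)
        }, character(1))
        cur[[v]][move] <- factor(new_lev, levels = levs)
      }
    }
    out[[t]] <- cbind(cur, round = t)
  }
  do.call(rbind, out)
}

# per-subject log-odds shifts, one column per (target, direction) pair
# present in the effects table
effect_linear_predictor <- function(effects, x) {
  if (is.null(effects) || nrow(effects) == 0) {
    return(matrix(0, nrow(x), 0))
  }
  keys <- unique(paste(effects$target, effects$direction, sep = "."))
  eta <- matrix(0, nrow(x), length(keys), dimnames = list(NULL, keys))
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    key <- paste(e$target, e$direction, sep = ".")
    val <- x[[e$covariate]]
    if (is.null(val)) stop("effect covariate not in panel: ", e$covariate)
    ind <- if (is.na(e$level) || e$level == "") as.numeric(val)
           else as.numeric(as.character(val) == e$level)
    eta[, key] <- eta[, key] + e$beta * ind
  }
  eta
}

# rescale one transition-matrix row so that the probability of being in
# the target group after the step has its logit shifted by delta; mass
# within each side of the split keeps its relative composition
modulate_split <- function(row, group, in_group_origin, delta) {
  states <- names(row)
  inside <- states %in% group
  if (in_group_origin) {
    p0 <- sum(row[!inside])   # probability of leaving the group
    if (p0 <= 0 || p0 >= 1) return(row)
    p <- stats::plogis(stats::qlogis(p0) + delta)
    row[!inside] <- row[!inside] * p / p0
    row[inside] <- row[inside] * (1 - p) / (1 - p0)
  } else {
    p0 <- sum(row[inside])    # probability of entering the group
    if (p0 <= 0 || p0 >= 1) return(row)
    p <- stats::plogis(stats::qlogis(p0) + delta)
    row[inside] <- row[inside] * p / p0
    row[!inside] <- row[!inside] * (1 - p) / (1 - p0)
  }
  row
}

# modulated transition row for one origin state and one eta profile;
# splits applied in fixed order stunting, overweight, cso
modulated_row <- function(P, from, eta_row) {
  row <- P[from, ]
  for (target in c("stunting", "overweight", "cso")) {
    group <- .target_groups[[target]]
    in_group <- from %in% group
    key <- paste(target, if (in_group) "exit" else "entry", sep = ".")
    delta <- if (key %in% names(eta_row)) eta_row[[key]] else 0
    if (delta != 0) row <- modulate_split(row, group, in_group, delta)
  }
  row
}

# vectorized one-step draw: subjects grouped by (origin state, eta profile)
draw_next_states <- function(from, P, eta) {
  n <- length(from)
  states <- nutritional_states()
  key <- if (ncol(eta) == 0) from else
    paste(from, apply(eta, 1, paste, collapse = "|"), sep = "|")
  nxt <- character(n)
  for (idx in split(seq_len(n), key)) {
    f <- from[idx[1]]
    eta_row <- if (ncol(eta) > 0) eta[idx[1], , drop = TRUE] else numeric(0)
    row <- modulated_row(P, f, as.list(eta_row))
    nxt[idx] <- sample(states, length(idx), replace = TRUE, prob = row)
  }
  nxt
}

#' Exact conditional transition matrix at a covariate profile
#'
#' Recomputes, deterministically from the generating configuration, the
#' 4x4 transition matrix that governed a given between-round interval for
#' subjects with a given covariate profile — the recovery oracle for
#' simulation studies.
#'
#' @param truth A \code{"sim_truth"} from \code{\link{simulate_cohort}}.
#' @param interval Interval index (1 = between rounds 1 and 2).
#' @param covariates One-row data frame (or list) with the covariate values
#'   at the origin round.
#' @return 4x4 row-stochastic matrix.
#' @export
true_transition_matrix <- function(truth, interval, covariates) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  P <- config$transition_matrices[[interval]]
  x <- as.data.frame(covariates, stringsAsFactors = FALSE)
  eta <- effect_linear_predictor(config$covariate_effects, x)
  out <- P
  for (from in nutritional_states()) {
    out[from, ] <- modulated_row(P, from,
                                 if (ncol(eta) > 0) as.list(eta[1, ]) else list())
  }
  out
}

#' Fill in anthropometry consistent with each row's nutritional state
#'
#' For every subject-round, draws a height-for-age z-score and the
#' age-appropriate weight index — weight-for-height z (under 5 years),
#' BMI-for-age z (5–19 years), or BMI in kg/m2 (over 19 years) — from
#' truncated normal distributions whose support matches the row's state
#' under the classification cutoffs (stunted implies HAZ < −2; overweight
#' implies WHZ > 2, BAZ > 1 or BMI > 25 by age band). Classifying the
#' generated measurements therefore reproduces the assigned state on every
#' row, which is the round-trip contract the classifier is tested against.
#'
#' @param panel Panel with \code{state} and \code{age_years} columns.
#' @param config The \code{\link{sim_config}} (reserved for distribution
#'   overrides; currently only validated).
#' @return The panel with \code{haz} and the band-appropriate one of
#'   \code{whz}/\code{baz}/\code{bmi} filled; out-of-band indices stay
#'   \code{NA}.
#' @export
simulate_anthropometry <- function(panel, config = NULL) {
  if (is.null(panel$age_years) || any(is.na(panel$age_years)) ||
      any(panel$age_years < 0)) {
    stop("every row needs a non-negative age_years")
  }
  if (is.null(panel$state) || any(is.na(panel$state))) {
    stop("every row needs a state")
  }
  st <- as.character(panel$state)
  stunted <- st %in% .target_groups$stunting
  ow <- st %in% .target_groups$overweight
  n <- nrow(panel)

  # HAZ: stunted side strictly below -2, other side at or above -2
  panel$haz <- ifelse(stunted,
                      rtrunc_norm(n, -2.9, 0.7, upper = -2),
                      rtrunc_norm(n, -0.7, 0.95, lower = -2))
  panel$haz[stunted & panel$haz >= -2] <- -2 - 1e-8

  band <- age_band(panel$age_years)
  for (b in c("whz", "baz", "bmi")) {
    sel <- band == b
    if (!any(sel)) next
    par <- switch(b,
      whz = list(cut = 2,  ow = c(2.6, 0.5),  no = c(0.2, 0.9)),
      baz = list(cut = 1,  ow = c(1.8, 0.6),  no = c(-0.2, 0.8)),
      bmi = list(cut = 25, ow = c(27.5, 2.0), no = c(20.5, 2.0)))
    v <- numeric(sum(sel))
    ows <- ow[sel]
    v[ows]  <- rtrunc_norm(sum(ows), par$ow[1], par$ow[2], lower = par$cut)
    v[!ows] <- rtrunc_norm(sum(!ows), par$no[1], par$no[2], upper = par$cut)
    v[ows & v <= par$cut] <- par$cut + 1e-8
    panel[[b]][sel] <- v
  }
  panel
}

# inverse-CDF truncated normal draw
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Apply monotone dropout and field-level missingness to a panel
#'
#' Subjects drop out between rounds with the configured per-interval
#' probability; once dropped, all later rounds are removed (no return).
#' Independently, each observed anthropometric field is blanked with the
#' configured missingness probability. Dropout can optionally depend on
#' covariates through log-odds shifts.
#'
#' Randomness continues the generator stream seeded by
#' \code{\link{simulate_cohort}}; seeding that function and replaying the
#' same stages reproduces the same attrition pattern.
#'
#' @param panel Panel from \code{\link{simulate_cohort}} (optionally after
#'   \code{\link{simulate_anthropometry}}).
#' @param config The \code{\link{sim_config}}.
#' @param dropout_effects Optional data frame (covariate, level, beta)
#'   shifting the per-round dropout probability on the logit scale.
#' @return The panel with dropped rows removed and missing fields blanked.
#' @export
apply_attrition <- function(panel, config, dropout_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$n_rounds
  panel <- panel[order(panel$subject_id, panel$round), , drop = FALSE]
  subjects <- unique(panel$subject_id)
  n <- length(subjects)

  # first dropped round per subject (R+1 = never)
  drop_round <- rep(R + 1L, n)
  active <- rep(TRUE, n)
  for (t in 2:R) {
    p <- rep(config$dropout_prob[t - 1], n)
    if (!is.null(dropout_effects) && nrow(dropout_effects) > 0) {
      x <- panel[panel$round == t - 1, , drop = FALSE]
      x <- x[match(subjects, x$subject_id), , drop = FALSE]
      eta <- rep(0, n)
      for (i in seq_len(nrow(dropout_effects))) {
        e <- dropout_effects[i, ]
        ind <- as.numeric(as.character(x[[e$covariate]]) == e$level)
        ind[is.na(ind)] <- 0
        eta <- eta + e$beta * ind
      }
      p <- stats::plogis(stats::qlogis(p) + eta)
    }
    gone <- active & (stats::runif(n) < p)
    drop_round[gone] <- t
    active <- active & !gone
  }
  keep <- panel$round < drop_round[match(panel$subject_id, subjects)]
  panel <- panel[keep, , drop = FALSE]

  if (config$missing_prob > 0) {
    for (v in c("haz", "whz", "baz", "bmi")) {
      obs <- which(!is.na(panel[[v]]))
      if (length(obs)) {
        blank <- obs[stats::runif(length(obs)) < config$missing_prob]
        panel[[v]][blank] <- NA_real_
      }
    }
  }
  rownames(panel) <- NULL
  panel
}
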