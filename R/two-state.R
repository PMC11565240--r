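#' Collapse a four-state panel to a two-state transition panel
#'
#' Builds the analysis table for one two-state model (stunted/not,
#' overweight/not, or cso/not): one row per retained subject per
#' between-round interval, with a binary origin indicator (in the target
#' state group at round t), a binary destination indicator (in the group
#' at round t+1), and the covariates measured at the origin round — the
#' covariate values that drive that interval's transition.
#'
#' The collapse keeps each condition's marginal definition: cso rows count
#' as "stunted" in the stunting model and as "overweight" in the
#' overweight model (see \code{\link{target_states}}).
#'
#' @param panel Complete-case classified panel with covariates.
#' @param target \code{"stunting"}, \code{"overweight"} or \code{"cso"}.
#' @param covariates Covariate columns carried into the rows.
#' @return Class \code{"two_state_panel"} data frame: subject_id,
#'   interval, origin, dest, covariates; attribute \code{target}.
#' @export
build_two_state_panel <- function(panel, target,
                                  covariates = c("sex", "wealth_q",
                                                 "residence", "hh_size")) {
  target <- match.arg(target, names(.target_groups))
  group <- .target_groups[[target]]
  panel <- panel[order(panel$subject_id, panel$round), , drop = FALSE]
  rounds <- sort(unique(panel$round))
  R <- length(rounds)
  if (any(table(panel$subject_id) != R)) {
    stop("panel must be complete-case (all rounds per subject)")
  }
  miss <- setdiff(covariates, names(panel))
  if (length(miss)) stop("covariates not in panel: ", paste(miss, collapse = ", "))
  in_group <- as.character(panel$state) %in% group
  n <- nrow(panel)
  idx_t <- which(panel$round != rounds[R])    # origin rows
  idx_t1 <- idx_t + 1L                        # matching destination rows
  out <- data.frame(
    subject_id = panel$subject_id[idx_t],
    interval = match(panel$round[idx_t], rounds),
    origin = as.integer(in_group[idx_t]),
    dest = as.integer(in_group[idx_t1]),
    stringsAsFactors = FALSE
  )
  for (v in covariates) out[[v]] <- panel[[v]][idx_t]
  attr(out, "target") <- target
  class(out) <- c("two_state_panel", "data.frame")
  out
}

# ---- logistic likelihood machinery (damped Newton on the score and
# observed information; the observed equals the expected information for
# the canonical logit link) ----

log1pexp <- function(eta) {
  ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
}

bernoulli_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1pexp(eta))
}

#' Maximum-likelihood logistic fit by damped Newton iterations
#'
#' Minimal Newton–Raphson engine for Bernoulli-logit likelihoods used by
#' the transition models and the screening regressions. Iterates
#' \code{beta <- beta + solve(I(beta), score(beta))} with step halving so
#' the log-likelihood never decreases; converges when the largest score
#' component falls below \code{tol_score} or the largest parameter change
#' below \code{tol_par}. Complete separation is detected as coefficients
#' diverging past \code{beta_max} and reported as non-estimable rather
#' than returned as huge finite estimates.
#'
#' @param X Design matrix (n x k).
#' @param y 0/1 response.
#' @param tol_score,tol_par,max_iter,beta_max Convergence and separation
#'   controls.
#' @return List: coef, se, vcov, loglik, converged, separation, singular,
#'   iterations, score_max.
#' @export
logit_newton <- function(X, y, tol_score = 1e-8, tol_par = 1e-10,
                         max_iter = 100L, beta_max = 15) {
  k <- ncol(X)
  beta <- rep(0, k)
  ll <- bernoulli_loglik(beta, X, y)
  separation <- FALSE
  singular <- FALSE
  converged <- FALSE
  iter <- 0L
  score_max <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - p))
    score_max <- max(abs(score))
    if (score_max < tol_score) { converged <- TRUE; break }
    w <- p * (1 - p)
    H <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    # halve the step until the log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- bernoulli_loglik(cand, X, y)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- ll_new
    if (max(abs(beta)) > beta_max) { separation <- TRUE; break }
    if (delta < tol_par) { converged <- TRUE; break }
  }
  p <- stats::plogis(drop(X %*% beta))
  score_max <- max(abs(drop(crossprod(X, y - p))))
  if (converged && score_max >= tol_score * 10) converged <- FALSE
  vcov <- se <- NULL
  if (!separation && !singular) {
    H <- crossprod(X * sqrt(p * (1 - p)))
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov)) singular <- TRUE else {
      dimnames(vcov) <- list(colnames(X), colnames(X))
      se <- sqrt(diag(vcov))
    }
  }
  list(coef = stats::setNames(beta, colnames(X)), se = se, vcov = vcov,
       loglik = bernoulli_loglik(beta, X, y),
       converged = converged && !separation && !singular,
       separation = separation, singular = singular,
       iterations = iter, score_max = score_max)
}

# design matrix: one intercept per interval (factor coding) plus
# covariates against their reference levels; factor levels frozen so
# prediction on new data uses the training contrasts
build_design <- function(data, covariates, interval_levels, xlevels = NULL) {
  df <- data.frame(interval_f = factor(data$interval, levels = interval_levels))
  for (v in covariates) {
    val <- data[[v]]
    if (is.numeric(val)) df[[v]] <- val
    else {
      lev <- if (!is.null(xlevels[[v]])) xlevels[[v]] else levels(factor(val))
      if (!all(as.character(val) %in% lev)) {
        stop("covariate level unseen in reference map for ", v)
      }
      df[[v]] <- factor(as.character(val), levels = lev)
    }
  }
  X <- stats::model.matrix(stats::reformulate(c("interval_f", covariates),
                                              intercept = TRUE), df)
  lv <- lapply(df[covariates[!vapply(df[covariates], is.numeric, TRUE)]], levels)
  list(X = X, xlevels = lv)
}

#' Fit the binary logit transition model for one target state
#'
#' Estimates, for transitions into and out of a target state group, the
#' model \code{logit P(in group at t+1 | origin, x_t) = alpha(t) + beta'
#' x_t}: interval-specific intercepts with covariate effects shared across
#' intervals, so each covariate yields a single odds ratio describing its
#' effect on transitioning relative to remaining in the origin state. The
#' entry direction uses subjects outside the group at the origin round
#' (outcome: entered); the exit direction uses subjects inside (outcome:
#' left). Each direction is an independent Bernoulli likelihood maximized
#' by \code{\link{logit_newton}}; standard errors come from the inverse
#' observed information.
#'
#' Directions with fewer than \code{min_events} observed events (or
#' non-events), or with detected separation, are flagged non-estimable —
#' reported as such rather than with unstable estimates.
#'
#' @param tsp A \code{\link{build_two_state_panel}} result.
#' @param covariates Covariate columns to adjust for (default: those in
#'   the panel); \code{character(0)} gives interval-intercept-only fits,
#'   which reproduce the empirical per-interval transition rates exactly.
#' @param min_events Minimum events and non-events per direction
#'   (default 5).
#' @param ... Passed to \code{\link{logit_newton}}.
#' @return Class \code{"two_state_fit"}: per-direction coefficient tables,
#'   log-likelihoods, AICs and diagnostics.
#' @seealso \code{\link{odds_ratio_table}}, \code{\link{run_adjusted_models}}
#' @export
fit_transition_logit <- function(tsp, covariates = NULL, min_events = 5L, ...) {
  target <- attr(tsp, "target")
  if (is.null(covariates)) {
    covariates <- setdiff(names(tsp), c("subject_id", "interval", "origin", "dest"))
  }
  interval_levels <- sort(unique(tsp$interval))
  fit_dir <- function(rows, y) {
    n_events <- sum(y)
    n_nonevents <- sum(1 - y)
    if (n_events < min_events || n_nonevents < min_events) {
      return(list(estimable = FALSE,
                  reason = sprintf("insufficient events (%d events / %d non-events, need %d)",
                                   n_events, n_nonevents, min_events),
                  n_obs = length(y), n_events = n_events))
    }
    d <- build_design(rows, covariates, interval_levels)
    nf <- logit_newton(d$X, y, ...)
    if (nf$separation || nf$singular || !nf$converged) {
      return(list(estimable = FALSE,
                  reason = if (nf$separation) "complete separation detected"
                           else if (nf$singular) "singular information (constant covariate?)"
                           else "did not converge",
                  n_obs = length(y), n_events = n_events, engine = nf))
    }
    k <- length(nf$coef)
    c(nf, list(estimable = TRUE, reason = "", n_obs = length(y),
               n_events = n_events, k = k, aic = 2 * k - 2 * nf$loglik,
               xlevels = d$xlevels))
  }
  entry_rows <- tsp[tsp$origin == 0L, , drop = FALSE]
  exit_rows <- tsp[tsp$origin == 1L, , drop = FALSE]
  fit <- structure(list(
    target = target,
    covariates = covariates,
    interval_levels = interval_levels,
    directions = list(
      entry = fit_dir(entry_rows, entry_rows$dest),
      exit = fit_dir(exit_rows, 1L - exit_rows$dest)
    )
  ), class = "two_state_fit")
  fit
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state logit transition model: %s\n", x$target))
  cat(sprintf("  covariates: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(interval intercepts only)"))
  for (d in names(x$directions)) {
    f <- x$directions[[d]]
    lab <- if (d == "entry") "into state" else "out of state"
    if (!f$estimable) {
      cat(sprintf("  %s: non-estimable (%s)\n", lab, f$reason))
    } else {
      cat(sprintf("  %s: n = %d, events = %d, loglik = %.2f, AIC = %.2f\n",
                  lab, f$n_obs, f$n_events, f$loglik, f$aic))
    }
  }
  invisible(x)
}

#' @export
summary.two_state_fit <- function(object, ...) {
  print(object)
  tab <- odds_ratio_table(object)
  if (nrow(tab)) {
    cat("\nOdds ratios (95% Wald CI):\n")
    print(tab, digits = 3, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.two_state_fit <- function(object, direction = c("entry", "exit"), ...) {
  direction <- match.arg(direction)
  f <- object$directions[[direction]]
  if (!isTRUE(f$estimable)) return(NULL)
  f$coef
}

#' @export
vcov.two_state_fit <- function(object, direction = c("entry", "exit"), ...) {
  direction <- match.arg(direction)
  f <- object$directions[[direction]]
  if (!isTRUE(f$estimable)) return(NULL)
  f$vcov
}

#' @export
confint.two_state_fit <- function(object, parm, level = 0.95,
                                  direction = c("entry", "exit"), ...) {
  direction <- match.arg(direction)
  f <- object$directions[[direction]]
  if (!isTRUE(f$estimable)) return(NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = f$coef - z * f$se, upper = f$coef + z * f$se)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.two_state_fit <- function(object, ...) {
  fs <- Filter(function(f) isTRUE(f$estimable), object$directions)
  ll <- sum(vapply(fs, `[[`, numeric(1), "loglik"))
  attr(ll, "df") <- sum(vapply(fs, `[[`, numeric(1), "k"))
  attr(ll, "nobs") <- sum(vapply(fs, `[[`, numeric(1), "n_obs"))
  class(ll) <- "logLik"
  ll
}

#' Predicted transition probabilities
#'
#' @param object A \code{"two_state_fit"}.
#' @param newdata Data frame with \code{interval} and the model covariates.
#' @param direction \code{"entry"} or \code{"exit"}.
#' @param ... Unused.
#' @return Probability of making the transition (entering or leaving the
#'   target state) for each row.
#' @export
predict.two_state_fit <- function(object, newdata,
                                  direction = c("entry", "exit"), ...) {
  direction <- match.arg(direction)
  f <- object$directions[[direction]]
  if (!isTRUE(f$estimable)) stop("direction is non-estimable: ", f$reason)
  d <- build_design(newdata, object$covariates, object$interval_levels,
                    xlevels = f$xlevels)
  stats::plogis(drop(d$X %*% f$coef))
}

#' Odds-ratio report for a fitted two-state model
#'
#' Exponentiates the covariate coefficients of each estimable direction
#' into odds ratios with 95\% Wald confidence intervals
#' \code{exp(beta +/- 1.96 se)}. Interval intercepts are omitted (they
#' parameterize baseline transition rates, not covariate effects).
#' Non-estimable directions appear as a single flagged row with the
#' reason, so small-sample directions are never reported with unstable
#' estimates.
#'
#' @param fit A \code{\link{fit_transition_logit}} result.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame: target, direction (\code{into}/\code{out_of}),
#'   term, beta, se, or, ci_low, ci_high, n_obs, estimable, reason.
#' @export
odds_ratio_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "two_state_fit"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (d in names(fit$directions)) {
    f <- fit$directions[[d]]
    lab <- if (d == "entry") "into" else "out_of"
    if (!isTRUE(f$estimable)) {
      rows[[d]] <- data.frame(target = fit$target, direction = lab,
                              term = NA_character_, beta = NA_real_,
                              se = NA_real_, or = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              n_obs = f$n_obs, estimable = FALSE,
                              reason = f$reason, stringsAsFactors = FALSE)
      next
    }
    keep <- !grepl("^\\(Intercept\\)$|^interval_f", names(f$coef))
    b <- f$coef[keep]; s <- f$se[keep]
    if (!length(b)) next
    rows[[d]] <- data.frame(target = fit$target, direction = lab,
                            term = names(b), beta = unname(b),
                            se = unname(s), or = exp(unname(b)),
                            ci_low = exp(unname(b) - z * unname(s)),
                            ci_high = exp(unname(b) + z * unname(s)),
                            n_obs = f$n_obs, estimable = TRUE, reason = "",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Fit adjusted two-state models for all malnourished targets
#'
#' Orchestrates \code{\link{build_two_state_panel}} +
#' \code{\link{fit_transition_logit}} + \code{\link{odds_ratio_table}}
#' for each requested target state, returning the fits and one combined
#' odds-ratio table. A sensitivity run adjusting for extra covariates
#' (e.g. maternal education) is the same call with an extended covariate
#' list.
#'
#' @param panel Complete-case classified panel with covariates.
#' @param targets Target states (default all three malnourished states).
#' @param covariates Adjustment set.
#' @param min_events Estimability threshold per direction.
#' @return List: \code{fits} (named by target) and \code{table}
#'   (combined odds-ratio data frame).
#' @export
run_adjusted_models <- function(panel,
                                targets = c("stunting", "overweight", "cso"),
                                covariates = c("sex", "wealth_q", "residence",
                                               "hh_size"),
                                min_events = 5L) {
  fits <- lapply(stats::setNames(targets, targets), function(tg) {
    tsp <- build_two_state_panel(panel, tg, covariates)
    fit_transition_logit(tsp, covariates, min_events = min_events)
  })
  tab <- do.call(rbind, lapply(fits, odds_ratio_table))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
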