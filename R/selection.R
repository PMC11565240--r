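#' Akaike information criterion
#'
#' \code{AIC = 2k - 2 loglik}. Used to compare candidate covariate sets;
#' preferred here over BIC for its milder penalty on extra parameters in
#' modest samples.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (>= 0).
#' @return The AIC value.
#' @export
#' @examples
#' aic(-100, 3)  # 206
aic <- function(loglik, k) {
  if (k < 0) stop("k must be non-negative")
  2 * k - 2 * loglik
}

#' Univariate baseline screening of candidate covariates
#'
#' For each candidate covariate, fits univariate logistic regressions of
#' baseline stunting and baseline overweight (each condition keeping its
#' marginal definition, so cso counts as both) and records the Wald
#' p-value of every non-reference level. A candidate passes the screen if
#' any of its levels is associated with either outcome at
#' \code{alpha} (default 0.05). Non-estimable fits (constant covariate,
#' separation) are flagged, not silently excluded.
#'
#' @param panel Classified panel.
#' @param candidates Candidate covariate columns.
#' @param alpha Screening significance level.
#' @param baseline_round Baseline round index (default 1).
#' @return Data frame: candidate, outcome, term, beta, se, p, estimable,
#'   passed (per candidate, repeated across its rows).
#' @export
univariate_screen <- function(panel,
                              candidates = c("sex", "wealth_q", "residence",
                                             "hh_size", "mat_edu"),
                              alpha = 0.05, baseline_round = 1L) {
  base <- panel[panel$round == baseline_round, , drop = FALSE]
  if (nrow(base) == 0) stop("no baseline rows")
  outcomes <- list(
    stunting = as.integer(as.character(base$state) %in% .target_groups$stunting),
    overweight = as.integer(as.character(base$state) %in% .target_groups$overweight)
  )
  rows <- list()
  for (cand in candidates) {
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      val <- base[[cand]]
      if (is.null(val)) stop("candidate column not found: ", cand)
      df <- data.frame(y = y, x = if (is.numeric(val)) val else factor(val))
      ok <- stats::complete.cases(df)
      df <- df[ok, , drop = FALSE]
      estimable <- TRUE
      terms <- data.frame()
      if ((is.factor(df$x) && nlevels(droplevels(df$x)) < 2) ||
          (is.numeric(df$x) && stats::var(df$x) == 0)) {
        estimable <- FALSE
      } else {
        X <- stats::model.matrix(~x, df)
        nf <- logit_newton(X, df$y)
        if (!nf$converged) estimable <- FALSE
        else {
          keep <- colnames(X) != "(Intercept)"
          b <- nf$coef[keep]; s <- nf$se[keep]
          terms <- data.frame(term = sub("^x", paste0(cand, ":"), names(b)),
                              beta = unname(b), se = unname(s),
                              p = 2 * stats::pnorm(-abs(unname(b) / unname(s))),
                              stringsAsFactors = FALSE)
        }
      }
      if (!estimable || nrow(terms) == 0) {
        terms <- data.frame(term = cand, beta = NA_real_, se = NA_real_,
                            p = NA_real_, stringsAsFactors = FALSE)
      }
      terms$candidate <- cand
      terms$outcome <- oc
      terms$estimable <- estimable
      rows[[paste(cand, oc)]] <- terms
    }
  }
  out <- do.call(rbind, rows)
  pass <- tapply(out$p, out$candidate, function(p) any(p < alpha, na.rm = TRUE))
  out$passed <- as.logical(pass[out$candidate])
  rownames(out) <- NULL
  out[, c("candidate", "outcome", "term", "beta", "se", "p", "estimable",
          "passed")]
}

#' Greedy forward covariate selection by AIC
#'
#' Starting from the interval-intercept-only two-state model for a target
#' state, repeatedly adds the candidate covariate that lowers the total
#' AIC (entry + exit directions) the most, stopping when no addition
#' lowers it. The whole ladder is logged. AIC ties within \code{1e-9} are
#' broken lexicographically by covariate name (deterministic, recorded in
#' the ladder). The fully adjusted model is also fitted and reported,
#' since presenting the full adjustment set for consistency across
#' targets — even when a smaller model fits marginally better in sparse
#' targets — is a common reporting choice; \code{final} switches which
#' model the report designates as final.
#'
#' @param panel Complete-case classified panel.
#' @param target Target state for the two-state model.
#' @param candidates Candidate covariates.
#' @param final \code{"fully_adjusted"} (default) or \code{"best_aic"}.
#' @param min_events Estimability threshold passed to the fitter.
#' @return Class \code{"selection_report"}: \code{ladder} (data frame of
#'   steps: step, added, aic, tie_break), \code{selected} (covariates in
#'   the best-AIC model), \code{final_covariates}, \code{final_fit}.
#' @export
stepwise_aic <- function(panel, target,
                         candidates = c("sex", "wealth_q", "residence",
                                        "hh_size"),
                         final = c("fully_adjusted", "best_aic"),
                         min_events = 5L) {
  final <- match.arg(final)
  tsp <- build_two_state_panel(panel, target, candidates)
  total_aic <- function(covs) {
    fit <- fit_transition_logit(tsp, covs, min_events = min_events)
    fs <- Filter(function(f) isTRUE(f$estimable), fit$directions)
    if (!length(fs)) return(list(aic = NA_real_, fit = fit))
    list(aic = sum(vapply(fs, `[[`, numeric(1), "aic")), fit = fit)
  }
  current <- character(0)
  base <- total_aic(current)
  if (is.na(base$aic)) stop("baseline model non-estimable for target ", target)
  ladder <- data.frame(step = 0L, added = "(intercepts only)", aic = base$aic,
                       tie_break = FALSE, stringsAsFactors = FALSE)
  best_aic <- base$aic
  remaining <- sort(candidates)   # lexicographic order fixes tie-breaks
  step <- 0L
  repeat {
    if (!length(remaining)) break
    trials <- vapply(remaining, function(cand) {
      total_aic(c(current, cand))$aic
    }, numeric(1))
    if (all(is.na(trials))) {
      ladder <- rbind(ladder, data.frame(step = step + 1L,
                                         added = "(all candidates non-estimable)",
                                         aic = NA_real_, tie_break = FALSE))
      break
    }
    best <- min(trials, na.rm = TRUE)
    if (best >= best_aic) break
    tied <- names(trials)[!is.na(trials) & abs(trials - best) < 1e-9]
    pick <- tied[1]                      # lexicographic among ties
    step <- step + 1L
    ladder <- rbind(ladder, data.frame(step = step, added = pick, aic = best,
                                       tie_break = length(tied) > 1,
                                       stringsAsFactors = FALSE))
    current <- c(current, pick)
    remaining <- setdiff(remaining, pick)
    best_aic <- best
  }
  full <- total_aic(candidates)
  final_covs <- if (final == "fully_adjusted") candidates else current
  structure(list(target = target, candidates = candidates, ladder = ladder,
                 selected = current, full_aic = full$aic,
                 final = final, final_covariates = final_covs,
                 final_fit = if (final == "fully_adjusted") full$fit
                             else total_aic(current)$fit),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Stepwise AIC selection for target '%s'\n", x$target))
  print(x$ladder, row.names = FALSE)
  cat(sprintf("best-AIC set: {%s}; fully adjusted AIC: %.2f\n",
              paste(x$selected, collapse = ", "), x$full_aic))
  cat(sprintf("final model reported: %s (%s)\n", x$final,
              paste(x$final_covariates, collapse = ", ")))
  invisible(x)
}
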