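#' Restrict a panel to complete cases (listwise deletion)
#'
#' Retains only subjects observed in every round with all required fields
#' non-missing in every round, mirroring the complete-case restriction
#' used when fitting Markov transition models to panel data. Every
#' excluded subject is logged with its first failing reason, checked in
#' the order: missing round, missing anthropometry (state), missing
#' covariate.
#'
#' @param panel Long-format panel with \code{subject_id}, \code{round} and
#'   a \code{state} column (see \code{\link{classify_panel}}).
#' @param scope \code{"states_only"} requires a state in every round;
#'   \code{"states_and_covariates"} additionally requires the covariates in
#'   \code{covariates} to be non-missing in every round.
#' @param covariates Covariate columns checked under
#'   \code{"states_and_covariates"}.
#' @param n_rounds Number of rounds a complete subject must have
#'   (default: the maximum round present).
#' @return List with \code{panel} (the retained rows) and \code{log}
#'   (class \code{"exclusion_log"}: per-subject reasons and per-reason
#'   counts). Retained + excluded subjects always partition the input.
#' @export
complete_case_filter <- function(panel,
                                 scope = c("states_and_covariates", "states_only"),
                                 covariates = c("sex", "wealth_q", "residence",
                                                "hh_size"),
                                 n_rounds = NULL) {
  scope <- match.arg(scope)
  if (nrow(panel) == 0) stop("empty panel")
  if (is.null(n_rounds)) n_rounds <- max(panel$round)
  rounds <- seq_len(n_rounds)
  if (scope == "states_only") covariates <- character(0)

  by_subj <- split(panel, panel$subject_id)
  reason <- vapply(by_subj, function(d) {
    if (!all(rounds %in% d$round)) return("missing round")
    if (any(is.na(d$state))) return("missing anthropometry")
    for (v in covariates) {
      if (is.null(d[[v]])) stop("covariate column absent: ", v)
      if (any(is.na(d[[v]]))) return("missing covariate")
    }
    ""
  }, character(1))

  kept_ids <- names(by_subj)[reason == ""]
  excl <- data.frame(subject_id = names(by_subj)[reason != ""],
                     reason = reason[reason != ""],
                     row.names = NULL, stringsAsFactors = FALSE)
  out <- panel[as.character(panel$subject_id) %in% kept_ids, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no subjects survive the complete-case filter; inspect the exclusion log")
  }
  rownames(out) <- NULL
  counts <- table(factor(excl$reason, levels = c("missing round",
                                                 "missing anthropometry",
                                                 "missing covariate")))
  log <- structure(list(excluded = excl, counts = counts,
                        n_input = length(by_subj), n_retained = length(kept_ids)),
                   class = "exclusion_log")
  list(panel = out, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Complete-case filter: %d of %d subjects retained (%.1f%%)\n",
              x$n_retained, x$n_input, 100 * x$n_retained / x$n_input))
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat(sprintf("  excluded, %s: %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

# Pearson chi-squared on an r x c count table; p undefined (NA) when the
# table has fewer than 2 rows or columns with observations
chisq_table_test <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                low_expected = NA))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, low_expected = any(res$expected < 5))
}

#' Baseline descriptive table with chi-squared tests
#'
#' Cross-tabulates covariates against the baseline (round 1) nutritional
#' state: counts with column percentages per state, plus a Pearson
#' chi-squared test of association (no continuity correction) per
#' variable. Variables with a single observed level get an undefined
#' p-value, reported as \code{NA}. A note flags tables with expected
#' counts below 5.
#'
#' @param panel Classified panel (or any data frame with a \code{state}
#'   and a \code{round} column).
#' @param variables Covariate columns to tabulate.
#' @param baseline_round Which round is baseline (default 1).
#' @return Class \code{"baseline_table"}: per-variable list of
#'   \code{counts}, \code{col_pct}, \code{statistic}, \code{df},
#'   \code{p.value}, \code{low_expected}.
#' @export
baseline_table <- function(panel,
                           variables = c("sex", "wealth_q", "residence",
                                         "hh_size", "mat_edu"),
                           baseline_round = 1L) {
  base <- panel[panel$round == baseline_round, , drop = FALSE]
  if (nrow(base) == 0) stop("no rows at the baseline round")
  make_entry <- function(v) {
    tab <- table(base[[v]], base$state)
    test <- chisq_table_test(tab)
    pct <- sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
    c(list(counts = tab, col_pct = pct), test)
  }
  out <- lapply(stats::setNames(variables, variables), make_entry)
  structure(list(variables = out, n = nrow(base),
                 state_totals = table(base$state)),
            class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, digits = 1, ...) {
  cat(sprintf("Baseline characteristics (n = %d)\n", x$n))
  tot <- x$state_totals
  cat("  state totals:",
      paste(sprintf("%s %d (%.1f%%)", names(tot), tot, 100 * tot / sum(tot)),
            collapse = ", "), "\n")
  for (v in names(x$variables)) {
    e <- x$variables[[v]]
    p <- if (is.na(e$p.value)) "p undefined (single level)"
         else if (e$p.value < 0.001) "p < 0.001"
         else sprintf("p = %.3f", e$p.value)
    cat(sprintf("  %s: chi-squared %.2f on %s df, %s%s\n", v,
                e$statistic, ifelse(is.na(e$df), "NA", e$df), p,
                if (isTRUE(e$low_expected)) " [expected count < 5]" else ""))
  }
  invisible(x)
}

#' Compare included and excluded subjects at baseline
#'
#' Builds, per covariate, the 2 x levels table of included vs excluded
#' subjects at baseline and tests it with Pearson chi-squared — the
#' standard check of whether complete-case restriction is associated with
#' observed characteristics. With no excluded subjects, p-values are
#' undefined and flagged.
#'
#' @param included,excluded Panels (only baseline rows are used; excluded
#'   may have incomplete rounds).
#' @param variables Covariate columns.
#' @param baseline_round Baseline round index (default 1).
#' @return Class \code{"baseline_table"} with included/excluded as the
#'   column dimension.
#' @export
attrition_comparison <- function(included, excluded,
                                 variables = c("sex", "wealth_q", "residence",
                                               "hh_size"),
                                 baseline_round = 1L) {
  pick_base <- function(d) {
    if (nrow(d) == 0) return(d)
    d[d$round == baseline_round, , drop = FALSE]
  }
  inc <- pick_base(included)
  exc <- pick_base(excluded)
  make_entry <- function(v) {
    lev <- unique(c(as.character(inc[[v]]), as.character(exc[[v]])))
    lev <- lev[!is.na(lev)]
    tab <- cbind(included = table(factor(inc[[v]], levels = lev)),
                 excluded = table(factor(exc[[v]], levels = lev)))
    test <- chisq_table_test(tab)
    pct <- sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
    c(list(counts = tab, col_pct = pct), test)
  }
  out <- lapply(stats::setNames(variables, variables), make_entry)
  structure(list(variables = out, n = nrow(inc) + nrow(exc),
                 state_totals = table(c(rep("included", nrow(inc)),
                                        rep("excluded", nrow(exc))))),
            class = "baseline_table")
}
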