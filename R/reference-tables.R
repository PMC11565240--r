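#' Published baseline cross-tabulation, India younger cohort
#'
#' Loads the bundled baseline characteristics table of the Young Lives
#' India younger cohort analytic sample (complete cases across all five
#' rounds, n = 1787): counts by baseline nutritional state for each
#' sociodemographic variable, as published. Used as a worked example for
#' the descriptive-table machinery — state shares and chi-squared
#' associations can be recomputed exactly from these counts.
#'
#' @return Data frame with columns variable, level, and one count column
#'   per state (normal, stunted, overweight, cso). The \code{"total"}
#'   variable row carries the column totals.
#' @export
#' @examples
#' tab <- india_yc_baseline_counts()
#' tot <- tab[tab$variable == "total", c("normal", "stunted", "overweight", "cso")]
#' round(100 * tot / sum(tot), 1)  # state shares in percent
india_yc_baseline_counts <- function() {
  path <- system.file("extdata", "india_yc_baseline_counts.csv",
                      package = "dbmtransit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Chi-squared association tests on a published count table
#'
#' Applies the same Pearson chi-squared test used by
#' \code{\link{baseline_table}} to each variable of a counts table in the
#' format of \code{\link{india_yc_baseline_counts}}.
#'
#' @param counts Data frame as returned by
#'   \code{\link{india_yc_baseline_counts}}.
#' @return Data frame: variable, statistic, df, p.value, low_expected.
#' @export
baseline_counts_tests <- function(counts) {
  states <- intersect(nutritional_states(), names(counts))
  vars <- setdiff(unique(counts$variable), "total")
  rows <- lapply(vars, function(v) {
    m <- as.matrix(counts[counts$variable == v, states])
    res <- chisq_table_test(m)
    data.frame(variable = v, statistic = res$statistic, df = res$df,
               p.value = res$p.value, low_expected = res$low_expected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
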