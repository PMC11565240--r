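#' LMS z-score transform
#'
#' Converts a raw measurement to a z-score against an LMS growth reference:
#' \code{z = ((x/M)^L - 1) / (L * S)}, with the continuous limit
#' \code{z = log(x/M) / S} used when \code{|L|} is below 1e-8.
#'
#' @param x Measurement (same units as M); must be positive.
#' @param L Box-Cox power.
#' @param M Reference median; positive.
#' @param S Reference coefficient of variation; positive.
#' @return z-score in SD units. Vectorized over all arguments.
#' @export
#' @examples
#' lms_zscore(110, L = 1, M = 100, S = 0.05)  # 2
#' lms_zscore(100, L = -1.6, M = 100, S = 0.1)  # 0: the median maps to 0
lms_zscore <- function(x, L, M, S) {
  k <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, k); L <- rep_len(L, k); M <- rep_len(M, k); S <- rep_len(S, k)
  if (any(x <= 0, na.rm = TRUE)) stop("measurement x must be positive")
  if (any(M <= 0, na.rm = TRUE) || any(S <= 0, na.rm = TRUE)) {
    stop("LMS parameters require M > 0 and S > 0")
  }
  z <- ifelse(abs(L) < 1e-8,
              log(x / M) / S,
              ((x / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Read a user-supplied LMS reference table
#'
#' Reads a CSV with columns \code{key} (age in years, or length/height),
#' \code{L}, \code{M}, \code{S}. Reference tables (e.g. WHO growth
#' standards) are supplied by the user and are not bundled.
#'
#' @param path CSV path.
#' @return Data frame sorted by key, class \code{"lms_table"}.
#' @export
read_lms_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "L", "M", "S")
  if (!all(need %in% names(tab))) {
    stop("LMS table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$M <= 0) || any(tab$S <= 0)) stop("LMS table requires M > 0, S > 0")
  tab <- tab[order(tab$key), need]
  class(tab) <- c("lms_table", "data.frame")
  tab
}

#' z-scores from measurements via an interpolated LMS table
#'
#' Linearly interpolates L, M and S at each key (age or height) between
#' tabulated rows, then applies \code{\link{lms_zscore}}. Keys outside the
#' tabulated range return \code{NA} with a warning.
#'
#' @param x Measurements.
#' @param key Lookup values (same scale as the table's key column).
#' @param table An \code{\link{read_lms_table}} result (or equivalent
#'   data frame).
#' @return z-scores, \code{NA} where the key is out of range.
#' @export
lms_zscore_lookup <- function(x, key, table) {
  rng <- range(table$key)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(key) & key >= rng[1] & key <= rng[2] & !is.na(x)
  if (any(!ok & !is.na(key))) {
    warning("keys outside the LMS table range return NA")
  }
  if (any(ok)) {
    L <- stats::approx(table$key, table$L, key[ok])$y
    M <- stats::approx(table$key, table$M, key[ok])$y
    S <- stats::approx(table$key, table$S, key[ok])$y
    out[ok] <- lms_zscore(x[ok], L, M, S)
  }
  out
}

# which weight index the age band uses: [0,5) WHZ, [5,19] BAZ, (19,Inf) BMI
age_band <- function(age_years) {
  ifelse(age_years < 5, "whz", ifelse(age_years <= 19, "baz", "bmi"))
}

#' Classify nutritional state from anthropometry
#'
#' Assigns each record exactly one of the four states from its
#' height-for-age z-score and the age-appropriate weight index:
#' stunted when HAZ < −2 SD; overweight when WHZ > 2 SD (under 5 years),
#' BMI-for-age z > 1 SD (5–19 years inclusive) or BMI > 25 kg/m2 (over
#' 19 years); cso when both criteria hold; normal when neither. All
#' cutoffs are strict inequalities, so HAZ exactly −2 is not stunted and
#' BAZ exactly 1 is not overweight.
#'
#' @param age_years Age in decimal years (non-negative).
#' @param haz Height-for-age z-score.
#' @param whz Weight-for-height z-score (used under 5 years).
#' @param baz BMI-for-age z-score (used at 5–19 years).
#' @param bmi BMI in kg/m2 (used over 19 years).
#' @return Factor over the four state levels. Vectorized; errors if HAZ or
#'   the band-appropriate weight index is missing (use
#'   \code{\link{classify_panel}} to flag instead of fail).
#' @export
#' @examples
#' classify_state(8, haz = -2.5, baz = 0.5)   # stunted
#' classify_state(8, haz = -2.5, baz = 1.5)   # cso
#' classify_state(22, haz = -1, bmi = 26)     # overweight
classify_state <- function(age_years, haz, whz = NA_real_, baz = NA_real_,
                           bmi = NA_real_) {
  k <- max(length(age_years), length(haz), length(whz), length(baz), length(bmi))
  age_years <- rep_len(age_years, k); haz <- rep_len(haz, k)
  whz <- rep_len(whz, k); baz <- rep_len(baz, k); bmi <- rep_len(bmi, k)
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop("age_years must be present and non-negative")
  }
  if (any(is.na(haz))) stop("HAZ is required for classification")
  band <- age_band(age_years)
  wi <- ifelse(band == "whz", whz, ifelse(band == "baz", baz, bmi))
  if (any(is.na(wi))) {
    i <- which(is.na(wi))[1]
    stop(sprintf("missing weight index '%s' for age band at age %.2f",
                 band[i], age_years[i]))
  }
  cut <- ifelse(band == "whz", 2, ifelse(band == "baz", 1, 25))
  stunted <- haz < -2
  over <- wi > cut
  st <- ifelse(stunted & over, "cso",
               ifelse(stunted, "stunted",
                      ifelse(over, "overweight", "normal")))
  as_state_factor(st)
}

#' Classify every subject-round of a panel
#'
#' Adds a \code{state} column using \code{\link{classify_state}}. Rows with
#' insufficient anthropometry (missing HAZ or the band-appropriate weight
#' index) are flagged in \code{state_missing} and keep \code{state = NA}
#' rather than being dropped — exclusion is the job of
#' \code{\link{complete_case_filter}}.
#'
#' @param panel Data frame with \code{age_years}, \code{haz} and the
#'   age-appropriate weight index columns (\code{whz}, \code{baz},
#'   \code{bmi}).
#' @param overwrite Recompute the state even if a state column exists
#'   (default TRUE).
#' @return The panel with \code{state} (factor) and \code{state_missing}
#'   (logical) columns.
#' @export
classify_panel <- function(panel, overwrite = TRUE) {
  if (!overwrite && !is.null(panel$state)) return(panel)
  for (v in c("whz", "baz", "bmi")) if (is.null(panel[[v]])) panel[[v]] <- NA_real_
  band <- age_band(panel$age_years)
  wi <- ifelse(band == "whz", panel$whz,
               ifelse(band == "baz", panel$baz, panel$bmi))
  ok <- !is.na(panel$haz) & !is.na(wi) & !is.na(panel$age_years)
  st <- rep(NA_character_, nrow(panel))
  if (any(ok)) {
    st[ok] <- as.character(classify_state(panel$age_years[ok], panel$haz[ok],
                                          panel$whz[ok], panel$baz[ok],
                                          panel$bmi[ok]))
  }
  panel$state <- as_state_factor(st)
  panel$state_missing <- !ok
  panel
}
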