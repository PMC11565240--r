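#' Nutritional state levels
#'
#' The four mutually exclusive nutritional states used throughout the
#' package, in canonical order: \code{"normal"}, \code{"stunted"},
#' \code{"overweight"}, \code{"cso"} (concurrently stunted and overweight).
#'
#' @return Character vector of the four state labels.
#' @export
#' @examples
#' nutritional_states()
nutritional_states <- function() {
  c("normal", "stunted", "overweight", "cso")
}

# Membership of each two-state collapse. Stunting keeps its marginal
# definition ({stunted, cso} are stunted); likewise overweight; cso is
# cso against everything else.
.target_groups <- list(
  stunting   = c("stunted", "cso"),
  overweight = c("overweight", "cso"),
  cso        = "cso"
)

#' States counted as "in state" for a two-state target
#'
#' Maps a two-state model target to the four-state levels it collapses to
#' the "in state" side. The stunting and overweight targets keep the
#' marginal definition of each condition, so the cso state belongs to both.
#'
#' @param target One of \code{"stunting"}, \code{"overweight"}, \code{"cso"}.
#' @return Character vector of four-state levels counted as the target state.
#' @export
#' @examples
#' target_states("stunting")   # stunted, cso
#' target_states("cso")        # cso only
target_states <- function(target) {
  target <- match.arg(target, names(.target_groups))
  .target_groups[[target]]
}

as_state_factor <- function(x) {
  factor(as.character(x), levels = nutritional_states())
}

# simple polynomial rolling hash used for config fingerprints in metadata
# (doubles stay exact below 2^53, so the modular arithmetic is exact)
.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
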