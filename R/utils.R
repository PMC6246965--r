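#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero on the
#' positive axis ("round half up"), the convention used for all reported
#' percentages. Base [round()] uses round-half-even, which would render
#' e.g. 0.125 as 0.12.
#'
#' @param x Numeric vector (non-negative in this package's usage).
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  # small epsilon guards against 55.605 being stored as 55.60499999...
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Format a percentage to two decimals
#'
#' @param x Percentage value(s) on the 0-100 scale.
#' @return Character vector like "16.01"; `NA` stays `NA`.
#' @export
format_pct <- function(x) {
  out <- ifelse(is.na(x), NA_character_,
                sprintf("%.2f", round_half_up(x, 2)))
  out
}

# meters per statute mile (exact)
METERS_PER_MILE <- 1609.344

meters_to_miles <- function(m) m / METERS_PER_MILE

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg) {
  stop(structure(
    class = c("carecapture_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
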