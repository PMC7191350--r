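#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the one-decimal column
#' percentages in surveillance reports. Base `round()` rounds half to even,
#' which would turn e.g. 1.45 into 1.4; reporting conventions require 1.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards against values like 1.4499999999 that are binary
  # representations of an exact .45
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' One-decimal column percentage
#'
#' @param n cell count.
#' @param denom column denominator.
#' @return `100 * n / denom` rounded half-up to one decimal.
#' @export
percent_1dp <- function(n, denom) {
  round_half_up(100 * n / denom, 1)
}

#' Format a count with its column percentage, "n (pct)"
#'
#' @param n cell count.
#' @param denom column denominator.
#' @return character, e.g. `"3533 (68.0)"`.
#' @export
format_count_pct <- function(n, denom) {
  sprintf("%d (%s)", as.integer(n),
          formatC(percent_1dp(n, denom), format = "f", digits = 1))
}

#' Format a p-value for table display
#'
#' Three decimals without a leading zero; values below 0.001 render as
#' `"<.001"`.
#'
#' @param p p-value in \[0, 1\].
#' @return character.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "—",
         ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p))))
}

# years elapsed between two dates (365.25-day years)
years_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / 365.25
}

# stop() with a consistent configuration-error prefix naming the field
config_error <- function(field, why) {
  stop(sprintf("configuration error in '%s': %s", field, why), call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
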