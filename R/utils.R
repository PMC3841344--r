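# Small shared helpers.

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; printed trial summaries use
#' conventional half-up rounding (7.5 minutes becomes 8).  This helper rounds
#' halves away from zero at a given number of decimal digits.
#'
#' @param x numeric vector.
#' @param digits integer, decimal digits to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(7.5)    # 8
#' round_half_up(0.105, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage to two decimals, half-up
#'
#' Formats a numerator/denominator pair the way cohort flow counts are
#' conventionally printed, e.g. 1175/1865 -> 63.00.
#'
#' @param num,den numerator and denominator counts.
#' @return numeric percentage rounded half-up to two decimals.
#' @export
pct2 <- function(num, den) {
  if (any(den == 0)) stop("percentage with zero denominator")
  round_half_up(100 * num / den, 2)
}

# Parse ISO-8601-ish timestamps at second resolution.  Accepts "T" or space
# separators; empty strings become NA (an open page view with no close stamp).
parse_timestamp <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp(s): ", paste(utils::head(unique(x[bad]), 3), collapse = ", "))
  }
  out
}

# Normal-quantile z for a two-sided confidence level.
z_quantile <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1, level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}
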