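#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; published epidemiological tables
#' round halves away from zero (23.45 -> 23.5). Used for all printed
#' percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, to one decimal
#' @param num,den numerator and denominator counts.
#' @return numeric percentage rounded half-away-from-zero to 1 decimal.
#' @export
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

# sample k elements of x without the length-1 surprise of sample()
resample <- function(x, k) x[sample.int(length(x), k)]

#' Completed years of age at a date
#'
#' @param date,birth_date Date vectors (recycled).
#' @return integer completed years.
#' @export
age_at <- function(date, birth_date) {
  as.integer(floor(as.numeric(date - birth_date) / 365.25))
}

# Fixed interval lengths used throughout: 1 year = 365 days, 6 months = 183
# days, 1 week = 7 days, 90 days literal. All windows are closed intervals.
DAYS_YEAR <- 365L
DAYS_HALF_YEAR <- 183L
DAYS_WEEK <- 7L

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
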