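#' First day (Monday) of the week containing a date
#'
#' Weeks run Monday through Sunday throughout the package; weekly activity
#' plans, cumulative weekly minutes and weekly summary messages all use this
#' convention.
#'
#' @param date a `Date` (or vector of dates).
#' @return the Monday of the same ISO week, as `Date`.
#' @export
week_start <- function(date) {
  date <- as.Date(date)
  date - (as.integer(format(date, "%u")) - 1L)
}

# 1 = Monday ... 7 = Sunday
weekday_index <- function(date) as.integer(format(as.Date(date), "%u"))

# round() in R rounds half to even; percent-of-goal uses conventional
# half-up rounding so 50.5% prints as 51.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
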