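#' Map calendar dates onto the 52-week analysis grid
#'
#' Interest panels are indexed by (year, week-of-year) on a fixed 52-week
#' grid: week 1 covers January 1--7, week 2 covers January 8--14, and so on,
#' with the final one or two days of the year folded into week 52. Week 53 is
#' never used. This deterministic day-of-year binning keeps the two study
#' years aligned week-for-week and avoids ISO-week edge cases.
#'
#' @param date a `Date` vector.
#' @return integer vector of week indices in `[1, 52]`.
#' @examples
#' week_of_year(as.Date(c("2020-01-01", "2020-03-15", "2019-12-25")))
#' @export
week_of_year <- function(date) {
  date <- as.Date(date)
  yd <- as.POSIXlt(date)$yday + 1L
  pmin(as.integer(ceiling(yd / 7)), 52L)
}

#' Reference holiday weeks on the 52-week grid
#'
#' The Christmas reference week is the grid week containing December 25 of the
#' baseline year; the Thanksgiving reference week (United States) is the grid
#' week containing the fourth Thursday of November.
#'
#' @param which `"christmas"` or `"thanksgiving"`.
#' @param year baseline calendar year (default 2019).
#' @return integer week index.
#' @examples
#' holiday_week("christmas")
#' holiday_week("thanksgiving")
#' @export
holiday_week <- function(which = c("christmas", "thanksgiving"), year = 2019L) {
  which <- match.arg(which)
  if (which == "christmas") {
    return(week_of_year(as.Date(sprintf("%d-12-25", year))))
  }
  # fourth Thursday of November
  nov <- as.Date(sprintf("%d-11-01", year)) + 0:29
  thursdays <- nov[as.POSIXlt(nov)$wday == 4L]
  week_of_year(thursdays[4L])
}
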