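#' Construct a weekly interest series
#'
#' An interest series holds the calibrated weekly search volume of one entity
#' or entity group in one country, on the 52-week grid of the two study years
#' (a baseline year and a treatment year). Calibrated volumes share a single
#' multiplicative scale, so series for different entities can be summed.
#'
#' @param country ISO country code (any non-empty string label).
#' @param label entity or group name.
#' @param year integer vector of years, one per observation.
#' @param week integer vector of week-of-year indices in `[1, 52]`.
#' @param volume numeric vector of non-negative calibrated volumes.
#' @return an object of class `interest_series`: a list with elements
#'   `country`, `label` and `data` (a tibble with columns `year`, `week`,
#'   `volume`, ordered by year then week).
#' @examples
#' s <- interest_series("US", "bread",
#'   year = rep(c(2019, 2020), each = 52),
#'   week = rep(1:52, 2), volume = runif(104, 50, 150)
#' )
#' s
#' @export
interest_series <- function(country, label, year, week, volume) {
  data <- tibble::tibble(
    year = as.integer(year),
    week = as.integer(week),
    volume = as.numeric(volume)
  )
  data <- data[order(data$year, data$week), ]
  out <- structure(
    list(country = country, label = label, data = data),
    class = "interest_series"
  )
  validate_interest_series(out)
}

validate_interest_series <- function(s) {
  stopifnot(inherits(s, "interest_series"))
  d <- s$data
  if (!is.character(s$country) || !nzchar(s$country)) {
    stop("interest_series: 'country' must be a non-empty string", call. = FALSE)
  }
  if (any(d$week < 1L | d$week > 52L)) {
    stop("interest_series '", s$label, "': weeks must lie in [1, 52]",
      call. = FALSE
    )
  }
  if (any(d$volume < 0)) {
    stop("interest_series '", s$label, "': volumes must be non-negative",
      call. = FALSE
    )
  }
  if (anyDuplicated(d[, c("year", "week")])) {
    stop("interest_series '", s$label,
      "': at most one observation per (year, week)",
      call. = FALSE
    )
  }
  s
}

#' @export
print.interest_series <- function(x, ...) {
  yrs <- sort(unique(x$data$year))
  cat(
    "<interest_series> ", x$label, " [", x$country, "]: ",
    nrow(x$data), " weekly observations, years ",
    paste(yrs, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

# volume for one (year, week); NA when absent
series_volume <- function(s, year, week) {
  i <- which(s$data$year == year & s$data$week == week)
  if (length(i) == 0L) NA_real_ else s$data$volume[i]
}

# TRUE when two series share exactly the same (year, week) grid
same_week_grid <- function(a, b) {
  identical(a$data[, c("year", "week")], b$data[, c("year", "week")])
}
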