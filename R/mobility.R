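#' Construct a daily mobility series
#'
#' Holds one country's daily residential mobility as the percent change of
#' time spent in residential areas relative to a pre-pandemic baseline (the
#' scale of the published community mobility reports). Dates must be strictly
#' increasing; calendar gaps are allowed but reported.
#'
#' @param country ISO country code.
#' @param date `Date` vector, strictly increasing.
#' @param residential numeric percent-change values.
#' @return an object of class `mobility_series`: a list with `country` and
#'   `data` (tibble with columns `date`, `residential`); the attribute
#'   `smoothed` records whether the values are a rolling average.
#' @export
mobility_series <- function(country, date, residential) {
  date <- as.Date(date)
  if (is.unsorted(date, strictly = TRUE)) {
    stop("mobility_series: dates must be strictly increasing", call. = FALSE)
  }
  n_gaps <- sum(diff(date) > 1)
  if (n_gaps > 0) {
    message(
      "mobility_series [", country, "]: ", n_gaps,
      " calendar gap(s) in the daily grid"
    )
  }
  structure(
    list(
      country = country,
      data = tibble::tibble(date = date, residential = as.numeric(residential))
    ),
    class = "mobility_series", smoothed = FALSE
  )
}

#' @export
print.mobility_series <- function(x, ...) {
  cat(
    "<mobility_series> [", x$country, "]: ", nrow(x$data), " days, ",
    format(min(x$data$date)), " to ", format(max(x$data$date)),
    if (isTRUE(attr(x, "smoothed"))) " (smoothed)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Weekly rolling average of a daily mobility series
#'
#' Applies a centered 7-day rolling mean. Edge days use the observations
#' available inside the window, requiring at least 4 of the 7 days.
#'
#' @param m a [mobility_series()] with at least 7 observations.
#' @return a smoothed [mobility_series()] (attribute `smoothed = TRUE`).
#' @export
smooth_weekly <- function(m) {
  stopifnot(inherits(m, "mobility_series"))
  if (nrow(m$data) < 7L) {
    stop("smooth_weekly: need at least 7 daily observations", call. = FALSE)
  }
  sm <- zoo::rollapply(m$data$residential,
    width = 7L, FUN = mean,
    align = "center", partial = 4L
  )
  out <- m
  out$data$residential <- as.numeric(sm)
  attr(out, "smoothed") <- TRUE
  out
}

#' Detect lockdown changepoints by smoothing and thresholding
#'
#' Works on the weekly rolling average of the residential series. The onset of
#' reduced mobility (`first_decrease`) is the first day the smoothed series
#' reaches the threshold (default +10 percent). The `mobility_increase` is the
#' first later day the series falls back below the threshold and stays below
#' for at least `min_run` days (brief dips shorter than that are ignored, with
#' a message); `second_decrease` is the first day after that at which the
#' series again reaches the threshold for at least `min_run` days. Fields are
#' `NA` when the corresponding crossing never happens.
#'
#' @param m a [mobility_series()]; smoothed internally when not already.
#' @param threshold percent threshold defining reduced mobility (default 10).
#' @param min_run minimum persistence, in days, for the relaxation and
#'   second-onset crossings (default 3).
#' @return an object of class `changepoint_set`: list with `Date` (or `NA`)
#'   fields `first_decrease`, `mobility_increase`, `second_decrease`, plus
#'   `peak_severity` (percent, `NA` when no onset) and `threshold`.
#' @export
detect_changepoints <- function(m, threshold = 10, min_run = 3L) {
  stopifnot(inherits(m, "mobility_series"))
  if (nrow(m$data) == 0L) {
    stop("detect_changepoints: empty series", call. = FALSE)
  }
  if (!isTRUE(attr(m, "smoothed"))) m <- smooth_weekly(m)
  x <- m$data$residential
  dates <- m$data$date
  n <- length(x)

  cp <- structure(
    list(
      first_decrease = as.Date(NA), mobility_increase = as.Date(NA),
      second_decrease = as.Date(NA), peak_severity = NA_real_,
      threshold = threshold, country = m$country
    ),
    class = "changepoint_set"
  )

  i1 <- which(x >= threshold)[1]
  if (is.na(i1)) {
    return(cp)
  }
  cp$first_decrease <- dates[i1]

  # first sustained drop below threshold after the onset
  i2 <- next_sustained(x < threshold, from = i1 + 1L, min_run = min_run)
  if (!is.na(i2)) {
    cp$mobility_increase <- dates[i2]
    i3 <- next_sustained(x >= threshold, from = i2 + 1L, min_run = min_run)
    if (!is.na(i3)) cp$second_decrease <- dates[i3]
  }

  end1 <- if (is.na(i2)) n else i2 - 1L
  cp$peak_severity <- max(x[i1:end1])
  cp
}

# index of the first TRUE run of length >= min_run (a run reaching the end of
# the series counts); NA when none; messages when short runs are skipped
next_sustained <- function(cond, from, min_run) {
  n <- length(cond)
  if (from > n) {
    return(NA_integer_)
  }
  skipped <- 0L
  i <- from
  while (i <= n) {
    if (cond[i]) {
      run_end <- i
      while (run_end < n && cond[run_end + 1L]) run_end <- run_end + 1L
      if (run_end - i + 1L >= min_run || run_end == n) {
        if (skipped > 0L) {
          message(
            "detect_changepoints: ignored ", skipped,
            " sub-threshold dip(s) shorter than the persistence window"
          )
        }
        return(i)
      }
      skipped <- skipped + 1L
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (skipped > 0L) {
    message(
      "detect_changepoints: ignored ", skipped,
      " crossing(s) shorter than the persistence window"
    )
  }
  NA_integer_
}

#' @export
print.changepoint_set <- function(x, ...) {
  fmt <- function(d) if (is.na(d)) "-" else format(d)
  cat(
    "<changepoint_set> [", x$country, "] onset: ", fmt(x$first_decrease),
    ", relaxation: ", fmt(x$mobility_increase),
    ", second onset: ", fmt(x$second_decrease),
    ", peak severity: ",
    if (is.na(x$peak_severity)) "-" else sprintf("%.1f%%", x$peak_severity),
    " (threshold ", x$threshold, "%)\n",
    sep = ""
  )
  invisible(x)
}

#' Lockdown severity: peak of the reduced-mobility period
#'
#' The maximum of the smoothed residential series between the onset of
#' reduced mobility and the mobility increase (or the end of the series).
#'
#' @param m a [mobility_series()]; smoothed internally when not already.
#' @param cp a `changepoint_set` for the same country.
#' @return percent severity (scalar).
#' @export
peak_severity <- function(m, cp) {
  stopifnot(inherits(m, "mobility_series"), inherits(cp, "changepoint_set"))
  if (is.na(cp$first_decrease)) {
    stop("peak_severity: no period of decreased mobility detected",
      call. = FALSE
    )
  }
  if (!isTRUE(attr(m, "smoothed"))) m <- smooth_weekly(m)
  upper <- if (is.na(cp$mobility_increase)) {
    max(m$data$date)
  } else {
    cp$mobility_increase - 1L
  }
  sel <- m$data$date >= cp$first_decrease & m$data$date <= upper
  max(m$data$residential[sel])
}

#' Read community-mobility-report CSVs
#'
#' Reads the published mobility-report dialect (columns
#' `country_region_code`, `date`, `residential_percent_change_from_baseline`,
#' optionally `sub_region_1`/`sub_region_2`). Sub-national rows (non-empty
#' sub-region fields) are dropped, keeping one country-level series per code.
#'
#' @param path CSV file path.
#' @return named list of [mobility_series()], keyed by country code.
#' @export
read_mobility_csv <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      # parsed via base strtod for exact decimal -> binary round-trips
      residential_percent_change_from_baseline = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c(
    "country_region_code", "date",
    "residential_percent_change_from_baseline"
  )
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_mobility_csv: missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df$residential_percent_change_from_baseline <-
    as.numeric(df$residential_percent_change_from_baseline)
  for (sub in intersect(c("sub_region_1", "sub_region_2"), names(df))) {
    df <- df[is.na(df[[sub]]) | df[[sub]] == "", ]
  }
  out <- lapply(split(df, df$country_region_code), function(g) {
    g <- g[order(g$date), ]
    mobility_series(
      g$country_region_code[1], g$date,
      g$residential_percent_change_from_baseline
    )
  })
  out
}

#' Write mobility series in the community-mobility-report dialect
#'
#' @param series a named list of [mobility_series()] (or a single one).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_mobility_csv <- function(series, path) {
  if (inherits(series, "mobility_series")) series <- list(series)
  rows <- lapply(series, function(m) {
    tibble::tibble(
      country_region_code = m$country,
      sub_region_1 = "",
      date = m$data$date,
      residential_percent_change_from_baseline =
        sprintf("%.17g", m$data$residential)
    )
  })
  readr::write_csv(do.call(rbind, rows), path, progress = FALSE)
  invisible(path)
}
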