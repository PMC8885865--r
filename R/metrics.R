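#' Surplus of interest: z-scores relative to the baseline year
#'
#' Standardises a two-year interest series by the mean and standard deviation
#' of its baseline-year (2019) weeks, so that every week of both years is
#' expressed in baseline standard deviations ("surplus of interest"). The
#' baseline-year z-values then have mean 0 and SD 1 by construction, and the
#' transform is invariant to the unknown multiplicative calibration factor
#' (any affine rescaling of volumes).
#'
#' @param s an [interest_series()] with at least two baseline-year weeks of
#'   non-zero variance.
#' @param baseline_year year used for the mean/SD (default 2019).
#' @return an object of class `zscore_series`: list with `country`, `label`,
#'   `mu`, `sigma` and `data` (tibble `year`, `week`, `z`).
#' @export
zscore_series <- function(s, baseline_year = 2019L) {
  stopifnot(inherits(s, "interest_series"))
  base <- s$data$volume[s$data$year == baseline_year]
  if (length(base) < 2L) {
    stop("zscore_series '", s$label, "': need >= 2 baseline-year weeks",
      call. = FALSE
    )
  }
  mu <- mean(base)
  sigma <- sd(base)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("zscore_series '", s$label, "': zero baseline-year variance",
      call. = FALSE
    )
  }
  structure(
    list(
      country = s$country, label = s$label, mu = mu, sigma = sigma,
      baseline_year = baseline_year,
      data = tibble::tibble(
        year = s$data$year, week = s$data$week,
        z = (s$data$volume - mu) / sigma
      )
    ),
    class = "zscore_series"
  )
}

#' @export
print.zscore_series <- function(x, ...) {
  cat(
    "<zscore_series> ", x$label, " [", x$country, "]: mu = ",
    signif(x$mu, 5), ", sigma = ", signif(x$sigma, 5),
    " (baseline ", x$baseline_year, ")\n",
    sep = ""
  )
  invisible(x)
}

zscore_at <- function(z, year, week) {
  i <- which(z$data$year == year & z$data$week == week)
  if (length(i) == 0L) {
    stop("zscore_series '", z$label, "': no observation at (", year, ", week ",
      week, ")",
      call. = FALSE
    )
  }
  z$data$z[i]
}

#' Surplus ratio of one week relative to a reference holiday week
#'
#' The surplus of interest in a week, relative to a reference week (typically
#' the Christmas week of the baseline year), is the ratio of the two
#' z-scores.
#'
#' @param z a [zscore_series()].
#' @param week,ref_week length-2 vectors `(year, week)`.
#' @return dimensionless ratio.
#' @export
surplus_ratio <- function(z, week, ref_week) {
  stopifnot(inherits(z, "zscore_series"))
  z_ref <- zscore_at(z, ref_week[1], ref_week[2])
  if (z_ref <= 0) {
    stop("surplus_ratio '", z$label,
      "': reference-week z-score is not positive; ratio undefined",
      call. = FALSE
    )
  }
  zscore_at(z, week[1], week[2]) / z_ref
}

#' Cumulative surplus ratio over a window of treatment-year weeks
#'
#' Sums the (signed) z-scores over a window of treatment-year weeks and
#' divides by the z-score of the reference week. Because the sum is signed,
#' the measure is additive over disjoint windows.
#'
#' @param z a [zscore_series()].
#' @param window integer vector of treatment-year weeks (e.g. `1:26` for the
#'   first half of the year).
#' @param ref_week length-2 `(year, week)` reference.
#' @param year treatment year of the window (default 2020).
#' @return dimensionless ratio.
#' @export
cumulative_surplus_ratio <- function(z, window, ref_week, year = 2020L) {
  stopifnot(inherits(z, "zscore_series"), length(window) >= 1L)
  z_ref <- zscore_at(z, ref_week[1], ref_week[2])
  if (z_ref <= 0) {
    stop("cumulative_surplus_ratio '", z$label,
      "': reference-week z-score is not positive; ratio undefined",
      call. = FALSE
    )
  }
  total <- sum(vapply(window, function(w) zscore_at(z, year, w), numeric(1)))
  total / z_ref
}

#' Year-over-year relative change in weekly interest
#'
#' For each week of the grid, the relative change of the treatment-year
#' volume over the corresponding baseline-year week,
#' `(y_2020 - y_2019) / y_2019`. Weeks with zero baseline volume are excluded
#' with a message. The country-level summary is the mean over the weekly
#' values with a t-based 95 percent confidence interval.
#'
#' @param s an [interest_series()] covering both years.
#' @param baseline_year,treatment_year the two years (defaults 2019, 2020).
#' @return list of class `relative_change` with `weekly` (tibble `week`,
#'   `change`), `mean`, `ci_low`, `ci_high`, `n`.
#' @export
relative_change <- function(s, baseline_year = 2019L, treatment_year = 2020L) {
  stopifnot(inherits(s, "interest_series"))
  d <- s$data
  base <- d[d$year == baseline_year, c("week", "volume")]
  trt <- d[d$year == treatment_year, c("week", "volume")]
  m <- merge(base, trt, by = "week", suffixes = c("_base", "_trt"))
  zero <- m$volume_base == 0
  if (any(zero)) {
    message(
      "relative_change '", s$label, "': excluded ", sum(zero),
      " week(s) with zero baseline volume"
    )
    m <- m[!zero, ]
  }
  if (nrow(m) == 0L) {
    stop("relative_change '", s$label, "': no usable weeks", call. = FALSE)
  }
  change <- (m$volume_trt - m$volume_base) / m$volume_base
  n <- length(change)
  mu <- mean(change)
  half <- if (n > 1) qt(0.975, n - 1) * sd(change) / sqrt(n) else 0
  structure(
    list(
      weekly = tibble::tibble(week = m$week, change = change),
      mean = mu, ci_low = mu - half, ci_high = mu + half, n = n
    ),
    class = "relative_change"
  )
}

#' @export
print.relative_change <- function(x, ...) {
  cat(
    sprintf(
      "<relative_change> mean %+.1f%% [%.1f%%, %.1f%%] over %d weeks\n",
      100 * x$mean, 100 * x$ci_low, 100 * x$ci_high, x$n
    )
  )
  invisible(x)
}
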