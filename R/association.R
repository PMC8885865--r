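#' Weekly means of a daily mobility series
#'
#' Collapses a daily mobility series onto the 52-week interest grid via
#' [week_of_year()], taking the mean of the available days in each week.
#' Weeks with no observed days are simply absent.
#'
#' @param m a [mobility_series()].
#' @param year restrict to this calendar year (default 2020).
#' @return tibble with columns `week`, `mobility`, `n_days`.
#' @export
weekly_mobility <- function(m, year = 2020L) {
  stopifnot(inherits(m, "mobility_series"))
  d <- m$data[as.POSIXlt(m$data$date)$year + 1900L == year, ]
  if (nrow(d) == 0L) {
    stop("weekly_mobility: no observations in ", year, call. = FALSE)
  }
  wk <- week_of_year(d$date)
  agg <- tapply(d$residential, wk, mean)
  tibble::tibble(
    week = as.integer(names(agg)),
    mobility = as.numeric(agg),
    n_days = as.integer(table(wk))
  )
}

#' Spearman rank test with t-distributed significance
#'
#' Spearman's rank correlation with average ranks for ties, tested against a
#' zero-correlation null with the t-statistic
#' `rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided).
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @return list of class `spearman_result`: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) {
    stop("spearman_test: need at least 4 paired observations", call. = FALSE)
  }
  rho <- cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf(
    "<spearman_result> rho = %.3f, p = %.3g, n = %d\n",
    x$rho, x$p_value, x$n
  ))
  invisible(x)
}

#' Seasonality-adjusted correlation between mobility and interest
#'
#' For each treatment-year week in `window`, the interest is expressed as the
#' relative change over the corresponding baseline-year week (removing
#' seasonal trends), and the weekly mean mobility is computed from the daily
#' series. The association is the Spearman rank correlation between the two,
#' with the t-based two-sided test of [spearman_test()]. The default window,
#' weeks 6--51, is the 46-week span from the first full week of February
#' through the end of December, the period the mobility reports cover.
#'
#' @param interest an [interest_series()] covering both years.
#' @param m a [mobility_series()] for the same country.
#' @param window integer vector of treatment-year weeks (default `6:51`).
#' @param baseline_year,treatment_year the two years (defaults 2019, 2020).
#' @return a `spearman_result`.
#' @export
mobility_interest_correlation <- function(interest, m, window = 6:51,
                                          baseline_year = 2019L,
                                          treatment_year = 2020L) {
  stopifnot(inherits(interest, "interest_series"))
  wm <- weekly_mobility(m, year = treatment_year)
  wm <- wm[wm$week %in% window, ]
  rel <- vapply(wm$week, function(w) {
    y0 <- series_volume(interest, baseline_year, w)
    y1 <- series_volume(interest, treatment_year, w)
    if (is.na(y0) || is.na(y1) || y0 <= 0) {
      return(NA_real_)
    }
    (y1 - y0) / y0
  }, numeric(1))
  spearman_test(wm$mobility, rel)
}

#' Dose-response between lockdown severity and estimated effects
#'
#' Cross-country association between the peak severity of reduced mobility
#' and the estimated short-term effect, as a Pearson correlation with a
#' two-sided t-test and a least-squares line. Outlier countries are excluded
#' only through the explicit `exclude` list and are always recorded in the
#' result. By default the association is computed on the log scale (the
#' fitted discontinuity jump itself), where a linear severity-effect coupling
#' is exactly linear; `scale = "linear"` uses the back-transformed percent
#' effect instead.
#'
#' @param severity named numeric vector, percent severity per country.
#' @param effects named list of `effect_estimate`s (or a named numeric vector
#'   of log-scale jumps) per country.
#' @param exclude character vector of country codes to exclude.
#' @param scale `"log"` (default) or `"linear"`.
#' @return list of class `dose_response_result`: `pearson_r`, `p_value`,
#'   `slope`, `intercept`, `excluded`, `n`, `scale`, `data` (tibble).
#' @export
dose_response <- function(severity, effects, exclude = character(),
                          scale = c("log", "linear")) {
  scale <- match.arg(scale)
  vals <- if (is.numeric(effects)) {
    effects
  } else {
    vapply(effects, function(e) {
      if (scale == "log") e$log_point else e$point
    }, numeric(1))
  }
  countries <- intersect(names(severity), names(vals))
  excluded <- intersect(exclude, countries)
  countries <- setdiff(countries, exclude)
  if (length(countries) < 3L) {
    stop("dose_response: need at least 3 countries after exclusion",
      call. = FALSE
    )
  }
  x <- as.numeric(severity[countries])
  y <- as.numeric(vals[countries])
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  line <- lm(y ~ x)
  structure(
    list(
      pearson_r = unname(ct$estimate),
      p_value = ct$p.value,
      slope = unname(coef(line)[2]),
      intercept = unname(coef(line)[1]),
      excluded = excluded,
      n = length(countries),
      scale = scale,
      data = tibble::tibble(country = countries, severity = x, effect = y)
    ),
    class = "dose_response_result"
  )
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf(
    "<dose_response_result> R = %.3f, p = %.3g, n = %d (%s scale)%s\n",
    x$pearson_r, x$p_value, x$n, x$scale,
    if (length(x$excluded)) {
      paste0("; excluded: ", paste(x$excluded, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}
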