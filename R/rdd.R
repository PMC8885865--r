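#' Specification of the difference-in-discontinuities model
#'
#' The model regresses weekly log interest on polynomial time trends that are
#' allowed to change at the cutoff (the onset of reduced mobility) and to
#' differ between the baseline and treatment years:
#'
#' `log y_tT = a' + b' t + g' t^2 + a'' i_t + b'' i_t t + g'' i_t t^2 +
#'  a''' j_T + b''' j_T t + g''' j_T t^2 + a i_t j_T + b i_t j_T t +
#'  g i_t j_T t^2`
#'
#' with `t` the week relative to the cutoff (`t = 0` is the cutoff week,
#' itself untreated), `i_t = 1` when `t > 0`, and `j_T = 1` in the treatment
#' year. The "fake" discontinuity in the baseline year removes seasonal
#' confounding; the interaction block `(a, b, g)` is the effect of the
#' mobility shock. `form = "linear"` drops the quadratic terms (8
#' coefficients) and `form = "constant"` keeps only the four intercept-style
#' terms.
#'
#' @param cutoff_week week-of-year of the cutoff in the treatment year.
#' @param form `"quadratic"` (default), `"linear"` or `"constant"`.
#' @param t_min weeks before the cutoff entering the fit (default 10, the
#'   largest pre-cutoff bandwidth available when the cutoff falls in March).
#' @param t_max weeks after the cutoff entering the fit (default 30, chosen
#'   so a second-wave shock never enters the window).
#' @param outcome `"log_volume"` or `"log_share"` (label only; the design is
#'   built from whatever volumes the series holds).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(cutoff_week,
                       form = c("quadratic", "linear", "constant"),
                       t_min = 10L, t_max = 30L,
                       outcome = c("log_volume", "log_share")) {
  form <- match.arg(form)
  outcome <- match.arg(outcome)
  t_min <- as.integer(t_min)
  t_max <- as.integer(t_max)
  if (t_min < 1L || t_max < 1L) {
    stop("model_spec: t_min and t_max must be >= 1", call. = FALSE)
  }
  if (form == "quadratic" && (t_min < 3L || t_max < 3L)) {
    stop("model_spec: quadratic form needs >= 3 distinct weeks on each side",
      call. = FALSE
    )
  }
  structure(
    list(
      cutoff_week = as.integer(cutoff_week), form = form,
      t_min = t_min, t_max = t_max, outcome = outcome
    ),
    class = "model_spec"
  )
}

#' Build the regression design from an interest series
#'
#' One row per (year, relative week `t`) for `t` in `[-t_min, t_max]`; the
#' default bandwidth yields `(10 + 30 + 1) * 2 = 82` rows. All volumes inside
#' the window must be present and strictly positive (the outcome is a log).
#'
#' @param s an [interest_series()] covering the window in both years.
#' @param spec a [model_spec()].
#' @param baseline_year,treatment_year the two years (defaults 2019, 2020).
#' @return tibble with columns `t`, `year`, `i_t`, `j_T`, `log_y`.
#' @export
build_design <- function(s, spec, baseline_year = 2019L,
                         treatment_year = 2020L) {
  stopifnot(inherits(s, "interest_series"), inherits(spec, "model_spec"))
  t_seq <- seq(-spec$t_min, spec$t_max)
  weeks <- spec$cutoff_week + t_seq
  if (any(weeks < 1L | weeks > 52L)) {
    stop("build_design '", s$label, "': window [",
      min(weeks), ", ", max(weeks),
      "] falls outside the 52-week grid; reduce t_min/t_max",
      call. = FALSE
    )
  }
  rows <- lapply(c(baseline_year, treatment_year), function(yr) {
    vol <- vapply(weeks, function(w) series_volume(s, yr, w), numeric(1))
    if (anyNA(vol)) {
      stop("build_design '", s$label, "': missing week(s) ",
        paste(weeks[is.na(vol)], collapse = ", "), " in ", yr,
        call. = FALSE
      )
    }
    if (any(vol <= 0)) {
      stop("build_design '", s$label, "': non-positive volume in ", yr,
        " week(s) ", paste(weeks[vol <= 0], collapse = ", "),
        call. = FALSE
      )
    }
    tibble::tibble(
      t = t_seq, year = yr,
      i_t = as.numeric(t_seq > 0),
      j_T = as.numeric(yr == treatment_year),
      log_y = log(vol)
    )
  })
  do.call(rbind, rows)
}

# regressor columns for a given form, in the model's canonical order
design_columns <- function(design, form) {
  t <- design$t
  i <- design$i_t
  j <- design$j_T
  cols <- list(
    alpha_base = rep(1, nrow(design)), beta_base = t, gamma_base = t^2,
    alpha_post = i, beta_post = i * t, gamma_post = i * t^2,
    alpha_year = j, beta_year = j * t, gamma_year = j * t^2,
    alpha = i * j, beta = i * j * t, gamma = i * j * t^2
  )
  keep <- switch(form,
    quadratic = names(cols),
    linear = grep("^(alpha|beta)", names(cols), value = TRUE),
    constant = grep("^alpha", names(cols), value = TRUE)
  )
  as.data.frame(cols[keep])
}

#' Fit the difference-in-discontinuities model by OLS
#'
#' Ordinary least squares with classical (homoskedastic) standard errors, as
#' in the study design this package implements. The full coefficient
#' covariance is retained for counterfactual contrasts.
#'
#' @param design a design tibble from [build_design()].
#' @param spec the [model_spec()] used to build it.
#' @return an object of class `rdd_fit`: list with `coefficients`,
#'   `standard_errors`, `covariance`, `n_obs`, `df_residual`,
#'   `residual_variance` and `spec`.
#' @export
fit_rdd <- function(design, spec) {
  stopifnot(inherits(spec, "model_spec"))
  X <- design_columns(design, spec$form)
  p <- ncol(X)
  n <- nrow(design)
  if (n < p + 2L) {
    stop("fit_rdd: need at least ", p + 2L, " observations for the ",
      spec$form, " form, got ", n,
      call. = FALSE
    )
  }
  df <- cbind(log_y = design$log_y, X)
  fit <- lm(log_y ~ . - 1, data = df)
  if (anyNA(coef(fit))) {
    stop("fit_rdd: rank-deficient design for the ", spec$form, " form",
      call. = FALSE
    )
  }
  cf <- coef(fit)
  names(cf) <- names(X)
  s2 <- sum(fit$residuals^2) / fit$df.residual
  V <- s2 * chol2inv(chol(crossprod(as.matrix(X))))
  dimnames(V) <- list(names(X), names(X))
  structure(
    list(
      coefficients = cf,
      standard_errors = sqrt(diag(V)),
      covariance = V,
      n_obs = n,
      df_residual = fit$df.residual,
      residual_variance = s2,
      spec = spec
    ),
    class = "rdd_fit"
  )
}

#' @export
print.rdd_fit <- function(x, ...) {
  cat(
    "<rdd_fit> form = ", x$spec$form, ", n = ", x$n_obs,
    ", cutoff week ", x$spec$cutoff_week, "\n",
    sep = ""
  )
  a <- x$coefficients["alpha"]
  cat(sprintf(
    "  shock jump alpha = %.4f (SE %.4f) -> short-term effect %+.1f%%\n",
    a, x$standard_errors["alpha"], 100 * (exp(a) - 1)
  ))
  invisible(x)
}

# mean-response regressor vector at (t, year); year via j in {0,1}
design_vector <- function(fit, t, j) {
  i <- as.numeric(t > 0)
  full <- c(
    alpha_base = 1, beta_base = t, gamma_base = t^2,
    alpha_post = i, beta_post = i * t, gamma_post = i * t^2,
    alpha_year = j, beta_year = j * t, gamma_year = j * t^2,
    alpha = i * j, beta = i * j * t, gamma = i * j * t^2
  )
  full[names(fit$coefficients)]
}

# point estimate, SE and +/- 2 SE interval of a linear contrast c'beta
contrast_estimate <- function(fit, cvec) {
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(drop(t(cvec) %*% fit$covariance %*% cvec))
  list(est = est, se = se, lo = est - 2 * se, hi = est + 2 * se)
}

effect_from_log <- function(log_est, log_se, df) {
  tstat <- if (log_se > 0) log_est / log_se else Inf * sign(log_est)
  p <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df) else 0
  if (log_est == 0 && log_se == 0) p <- 1
  structure(
    list(
      point = exp(log_est) - 1,
      ci_low = exp(log_est - 2 * log_se) - 1,
      ci_high = exp(log_est + 2 * log_se) - 1,
      p_value = p,
      significant = p < 0.05,
      log_point = log_est,
      log_se = log_se
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate> %+.1f%% [%+.1f%%, %+.1f%%], p = %.3g%s\n",
    100 * x$point, 100 * x$ci_low, 100 * x$ci_high, x$p_value,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Short-term effect of the mobility shock
#'
#' Converts the fitted interaction jump `alpha` to the multiplicative scale:
#' the point estimate is `exp(alpha) - 1`, the 95 percent interval is the
#' back-transformed `alpha +/- 2 SE`, and the p-value is a two-sided t-test
#' on `alpha`.
#'
#' @param fit an [fit_rdd()] result.
#' @return an `effect_estimate` with fields `point`, `ci_low`, `ci_high`,
#'   `p_value`, `significant`, and the log-scale `log_point`, `log_se`.
#' @export
short_term_effect <- function(fit) {
  stopifnot(inherits(fit, "rdd_fit"))
  effect_from_log(
    fit$coefficients[["alpha"]],
    fit$standard_errors[["alpha"]],
    fit$df_residual
  )
}

#' Fitted treatment-year value vs the baseline-year counterfactual
#'
#' At a post-cutoff week `t`, the fitted mean log outcome of the treatment
#' year and of the baseline-year counterfactual, each with a 95 percent
#' interval (+/- 2 SE from the coefficient covariance). The two are "no
#' longer significantly different" when the intervals overlap.
#'
#' @param fit an [fit_rdd()] result.
#' @param t post-cutoff week, `0 < t <= t_max`.
#' @return list of class `gap_estimate`: `t`, `gap_2020`, `gap_2019`,
#'   `ci_2020`, `ci_2019` (length-2), `overlapping`.
#' @export
counterfactual_gap <- function(fit, t) {
  stopifnot(inherits(fit, "rdd_fit"))
  if (t <= 0 || t > fit$spec$t_max) {
    stop("counterfactual_gap: t must lie in (0, t_max]", call. = FALSE)
  }
  e20 <- contrast_estimate(fit, design_vector(fit, t, j = 1))
  e19 <- contrast_estimate(fit, design_vector(fit, t, j = 0))
  overlapping <- e20$lo <= e19$hi && e19$lo <= e20$hi
  structure(
    list(
      t = t, gap_2020 = e20$est, gap_2019 = e19$est,
      ci_2020 = c(e20$lo, e20$hi), ci_2019 = c(e19$lo, e19$hi),
      overlapping = overlapping
    ),
    class = "gap_estimate"
  )
}

#' Weeks until interest reverts to the seasonal counterfactual
#'
#' Scans `t = 1, ..., t_max` for the first week from which the treatment-year
#' fit and the baseline-year counterfactual have overlapping 95 percent
#' intervals at that week and all later weeks (sustained reversion). Returns
#' status `"never_differed"` when the intervals already overlap at `t = 1`,
#' `"not_reverted"` when they still disagree at `t_max`, and `"reverted"`
#' with the week otherwise. When a transient single-week overlap would give
#' an earlier answer than the sustained criterion, a message reports both.
#'
#' @param fit an [fit_rdd()] result.
#' @return list of class `reversion_time` with `status` and `weeks`
#'   (`NA` unless status is `"reverted"`).
#' @export
reversion_time <- function(fit) {
  stopifnot(inherits(fit, "rdd_fit"))
  t_max <- fit$spec$t_max
  overlaps <- vapply(
    seq_len(t_max),
    function(t) counterfactual_gap(fit, t)$overlapping,
    logical(1)
  )
  sustained_from <- rev(cumprod(rev(overlaps))) > 0
  first_sustained <- which(sustained_from)[1]
  first_overlap <- which(overlaps)[1]
  if (!is.na(first_overlap) && !is.na(first_sustained) &&
    first_overlap != first_sustained) {
    message(
      "reversion_time: first overlap at week ", first_overlap,
      " but sustained only from week ", first_sustained
    )
  }
  if (is.na(first_sustained)) {
    status <- "not_reverted"
    weeks <- NA_integer_
  } else if (first_sustained == 1L) {
    status <- "never_differed"
    weeks <- NA_integer_
  } else {
    status <- "reverted"
    weeks <- as.integer(first_sustained)
  }
  structure(
    list(status = status, weeks = weeks),
    class = "reversion_time"
  )
}

#' @export
print.reversion_time <- function(x, ...) {
  cat(
    "<reversion_time> ",
    switch(x$status,
      reverted = paste0("reverted after ", x$weeks, " weeks"),
      never_differed = "never significantly differed",
      not_reverted = "not reverted within the modeled window"
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Long-term effect at the end of the modeled window
#'
#' How elevated the fitted treatment-year interest remains at `t_max`
#' relative to the baseline-year fit at the same week, on the multiplicative
#' scale: `exp(contrast) - 1` where the contrast is the difference of the two
#' fitted mean log outcomes, with a +/- 2 SE interval from the coefficient
#' covariance and a two-sided t-test p-value.
#'
#' @param fit an [fit_rdd()] result.
#' @return an `effect_estimate`.
#' @export
long_term_effect <- function(fit) {
  stopifnot(inherits(fit, "rdd_fit"))
  t <- fit$spec$t_max
  cvec <- design_vector(fit, t, j = 1) - design_vector(fit, t, j = 0)
  e <- contrast_estimate(fit, cvec)
  effect_from_log(e$est, e$se, fit$df_residual)
}

#' Share-of-interest outcome variant
#'
#' Replaces a group's absolute volume by its share of the total food volume
#' in the same country and week, controlling for the overall surge of food
#' interest. The result is an ordinary interest series usable with
#' `outcome = "log_share"`.
#'
#' @param group,total_food two [interest_series()] on the same week grid;
#'   `total_food` must be week-wise positive and at least the group volume.
#' @return an [interest_series()] of week-wise shares in `[0, 1]`.
#' @export
share_outcome <- function(group, total_food) {
  stopifnot(
    inherits(group, "interest_series"),
    inherits(total_food, "interest_series")
  )
  if (!same_week_grid(group, total_food)) {
    stop("share_outcome: mismatched week grids", call. = FALSE)
  }
  if (any(total_food$data$volume <= 0)) {
    stop("share_outcome: total food volume must be positive in every week",
      call. = FALSE
    )
  }
  if (any(group$data$volume > total_food$data$volume + 1e-9)) {
    stop("share_outcome: group volume exceeds the total in some week",
      call. = FALSE
    )
  }
  interest_series(
    country = group$country, label = paste0(group$label, "_share"),
    year = group$data$year, week = group$data$week,
    volume = group$data$volume / total_food$data$volume
  )
}
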