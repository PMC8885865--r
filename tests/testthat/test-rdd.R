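test_that("default design has 82 rows with correct indicator coding", {
  s <- generate_interest_series(shock_params())
  spec <- default_spec()
  d <- build_design(s, spec)
  expect_equal(nrow(d), 82)
  expect_equal(sort(unique(d$t)), -10:30)
  # t = 0 (cutoff week) is untreated even in the treatment year
  expect_equal(d$i_t[d$t == 0 & d$year == 2020], 0)
  expect_equal(d$j_T[d$t == 0 & d$year == 2020], 1)
  expect_equal(d$i_t[d$t == 5 & d$year == 2019], 1)
  expect_equal(d$j_T[d$t == 5 & d$year == 2019], 0)
  expect_true(all(d$i_t == as.numeric(d$t > 0)))
  expect_true(all(d$j_T == as.numeric(d$year == 2020)))
})

test_that("design construction rejects bad windows and volumes", {
  s <- generate_interest_series(shock_params())
  # window spilling off the 52-week grid
  expect_error(
    build_design(s, model_spec(cutoff_week = 25, t_max = 30)),
    "outside the 52-week grid"
  )
  # missing weeks inside the window
  trimmed <- s
  trimmed$data <- trimmed$data[
    !(trimmed$data$year == 2020 & trimmed$data$week == 20),
  ]
  expect_error(build_design(trimmed, default_spec()), "missing week")
  # zero volume inside the window names the week
  zeroed <- s
  zeroed$data$volume[zeroed$data$year == 2019 & zeroed$data$week == 15] <- 0
  expect_error(build_design(zeroed, default_spec()), "non-positive")
})

test_that("identical years give zero treatment-year interactions", {
  s <- generate_interest_series(shock_params(alpha = 0))
  for (form in c("quadratic", "linear", "constant")) {
    spec <- default_spec(form = form)
    fit <- fit_rdd(build_design(s, spec), spec)
    year_block <- grep("year|^alpha$|^beta$|^gamma$",
      names(fit$coefficients),
      value = TRUE
    )
    expect_true(all(abs(fit$coefficients[year_block]) < 1e-8))
  }
})

test_that("nested-model recovery: injected shock is recovered exactly", {
  s <- generate_interest_series(
    shock_params(alpha = 0.5, beta = 0, gamma = 0)
  )
  spec <- default_spec()
  fit <- fit_rdd(build_design(s, spec), spec)
  expect_lt(abs(fit$coefficients[["alpha"]] - 0.5), 1e-8)
  expect_lt(abs(fit$coefficients[["beta"]]), 1e-8)
  expect_lt(abs(fit$coefficients[["gamma"]]), 1e-8)
  # zero residual variance: the generative model is nested in the fit
  expect_lt(fit$residual_variance, 1e-16)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      s <- generate_interest_series(
        shock_params(
          alpha = rnorm(1, 0, 0.5), beta = rnorm(1, 0, 0.02),
          gamma = rnorm(1, 0, 5e-4), sigma = 0.15,
          seed = sample.int(1e6, 1)
        )
      )
      form <- sample(c("quadratic", "linear", "constant"), 1)
      spec <- default_spec(form = form)
      design <- build_design(s, spec)
      fit <- fit_rdd(design, spec)
      X <- as.matrix(dietshift:::design_columns(design, form))
      oracle <- drop(normal_equations_fit(X, design$log_y))
      expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
    }
  })
})

test_that("constant-form alpha is the hand-computed difference in differences", {
  withr::with_seed(33, {
    s <- generate_interest_series(
      shock_params(alpha = 0.3, sigma = 0.2, seed = 77L)
    )
  })
  spec <- default_spec(form = "constant")
  design <- build_design(s, spec)
  fit <- fit_rdd(design, spec)
  mean_cell <- function(i, j) {
    mean(design$log_y[design$i_t == i & design$j_T == j])
  }
  did <- (mean_cell(1, 1) - mean_cell(0, 1)) -
    (mean_cell(1, 0) - mean_cell(0, 0))
  expect_equal(fit$coefficients[["alpha"]], did, tolerance = 1e-10)
})

test_that("short-term effect converts the jump to the multiplicative scale", {
  s <- generate_interest_series(shock_params(alpha = log(2)))
  spec <- default_spec()
  eff <- short_term_effect(fit_rdd(build_design(s, spec), spec))
  expect_equal(eff$point, 1.0, tolerance = 1e-9) # +100%
  s0 <- generate_interest_series(shock_params(alpha = log(1.5)))
  eff0 <- short_term_effect(fit_rdd(build_design(s0, spec), spec))
  expect_equal(eff0$point, 0.5, tolerance = 1e-9) # +50%
  # CI endpoints are the back-transformed alpha +/- 2 SE
  sn <- generate_interest_series(shock_params(alpha = 0.4, sigma = 0.1))
  fitn <- fit_rdd(build_design(sn, spec), spec)
  en <- short_term_effect(fitn)
  a <- fitn$coefficients[["alpha"]]
  se <- fitn$standard_errors[["alpha"]]
  expect_equal(en$ci_low, exp(a - 2 * se) - 1)
  expect_equal(en$ci_high, exp(a + 2 * se) - 1)
  expect_true(en$ci_low <= en$point && en$point <= en$ci_high)
})

test_that("counterfactual gap intervals match the explicit quadratic form", {
  sn <- generate_interest_series(shock_params(alpha = 0.4, sigma = 0.1))
  spec <- default_spec()
  fit <- fit_rdd(build_design(sn, spec), spec)
  for (t in c(1, 7, 15, 30)) {
    g <- counterfactual_gap(fit, t)
    for (j in c(1, 0)) {
      x <- c(
        1, t, t^2,
        (t > 0), (t > 0) * t, (t > 0) * t^2,
        j, j * t, j * t^2,
        (t > 0) * j, (t > 0) * j * t, (t > 0) * j * t^2
      )
      est <- sum(x * fit$coefficients)
      se <- sqrt(drop(t(x) %*% fit$covariance %*% x))
      if (j == 1) {
        expect_equal(g$gap_2020, est, tolerance = 1e-8)
        expect_equal(g$ci_2020, c(est - 2 * se, est + 2 * se),
          tolerance = 1e-8
        )
      } else {
        expect_equal(g$gap_2019, est, tolerance = 1e-8)
        expect_equal(g$ci_2019, c(est - 2 * se, est + 2 * se),
          tolerance = 1e-8
        )
      }
    }
  }
  expect_error(counterfactual_gap(fit, 0), "t must lie")
  expect_error(counterfactual_gap(fit, 31), "t must lie")
})

test_that("identical years overlap everywhere; big slow shocks do not at t = 1", {
  same <- generate_interest_series(shock_params(sigma = 0.05, seed = 9L))
  spec <- default_spec()
  fit_same <- fit_rdd(build_design(same, spec), spec)
  expect_true(all(sapply(1:30, function(t) {
    counterfactual_gap(fit_same, t)$overlapping
  })))
  expect_equal(reversion_time(fit_same)$status, "never_differed")
  big <- generate_interest_series(
    shock_params(alpha = 2, sigma = 0.01, seed = 4L)
  )
  fit_big <- fit_rdd(build_design(big, spec), spec)
  expect_false(counterfactual_gap(fit_big, 1)$overlapping)
  expect_equal(reversion_time(fit_big)$status, "not_reverted")
})

test_that("reversion week tracks where the decaying shock drops below CI resolution", {
  alpha <- 0.5
  sigma <- 0.01
  # shock alpha (1 - t/30)^2: monotone decay hitting zero exactly at t = 30
  beta <- -2 * alpha / 30
  gamma <- alpha / 30^2
  spec <- default_spec()
  # oracle for the expected reversion week from the design geometry alone:
  # the shock size vs the width of the two +/- 2 SE mean-response bands
  s0 <- generate_interest_series(shock_params())
  X <- as.matrix(dietshift:::design_columns(build_design(s0, spec), "quadratic"))
  xtx_inv <- solve(crossprod(X))
  unit_se <- function(t, j) {
    x <- c(
      1, t, t^2, (t > 0), (t > 0) * t, (t > 0) * t^2,
      j, j * t, j * t^2, (t > 0) * j, (t > 0) * j * t, (t > 0) * j * t^2
    )
    sqrt(drop(t(x) %*% xtx_inv %*% x))
  }
  shock <- function(t) alpha * (1 - t / 30)^2
  resolvable <- sapply(1:30, function(t) {
    shock(t) > 2 * sigma * (unit_se(t, 1) + unit_se(t, 0))
  })
  expected_week <- which(!resolvable)[1]
  expect_false(is.na(expected_week))

  detected <- sapply(1:20, function(r) {
    s <- generate_interest_series(
      shock_params(alpha = alpha, beta = beta, gamma = gamma,
        sigma = sigma, seed = 100L + r
      )
    )
    rv <- reversion_time(fit_rdd(build_design(s, spec), spec))
    rv$weeks
  })
  expect_lte(abs(median(detected, na.rm = TRUE) - expected_week), 1)
})

test_that("long-term effect: permanent shock persists, identical years give zero", {
  spec <- default_spec()
  perm <- generate_interest_series(shock_params(alpha = 0.3))
  lte <- long_term_effect(fit_rdd(build_design(perm, spec), spec))
  expect_equal(lte$point, exp(0.3) - 1, tolerance = 1e-9)
  same <- generate_interest_series(shock_params())
  lte0 <- long_term_effect(fit_rdd(build_design(same, spec), spec))
  expect_equal(lte0$point, 0, tolerance = 1e-9)
  # contrast variance matches the brute-force quadratic form
  noisy <- generate_interest_series(shock_params(alpha = 0.3, sigma = 0.1))
  fit <- fit_rdd(build_design(noisy, spec), spec)
  lten <- long_term_effect(fit)
  t <- 30
  cvec <- c(
    0, 0, 0, 0, 0, 0,
    1, t, t^2, 1, t, t^2
  )
  se <- sqrt(drop(t(cvec) %*% fit$covariance %*% cvec))
  est <- sum(cvec * fit$coefficients)
  expect_equal(lten$log_se, se, tolerance = 1e-10)
  expect_equal(lten$point, exp(est) - 1, tolerance = 1e-10)
})

test_that("effect CI coverage sits near the nominal 95 percent", {
  spec <- default_spec()
  true_alpha <- log(1.5)
  hits <- vapply(1:300, function(r) {
    s <- generate_interest_series(
      shock_params(alpha = true_alpha, sigma = 0.1, seed = 5000L + r)
    )
    e <- short_term_effect(fit_rdd(build_design(s, spec), spec))
    e$ci_low <= 0.5 && 0.5 <= e$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("estimator bias at +50 percent truth is below 2 points", {
  spec <- default_spec()
  est <- vapply(1:300, function(r) {
    s <- generate_interest_series(
      shock_params(alpha = log(1.5), sigma = 0.1, seed = 9000L + r)
    )
    short_term_effect(fit_rdd(build_design(s, spec), spec))$point
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.02)
})

test_that("share outcome is the week-wise ratio with partition closure", {
  g <- make_series(c(10, 20, 30), c(10, 20, 30), label = "g")
  tot <- make_series(c(100, 100, 100), c(100, 100, 100), label = "tot")
  sh <- share_outcome(g, tot)
  expect_equal(sh$data$volume, rep(c(0.1, 0.2, 0.3), 2))
  expect_equal(share_outcome(tot, tot)$data$volume, rep(1, 6))
  expect_error(
    share_outcome(g, make_series(c(0, 100, 100))),
    "positive"
  )
  # shares of a partition sum to one in every week
  withr::with_seed(55, {
    parts <- lapply(1:4, function(i) {
      make_series(runif(52, 5, 50), runif(52, 5, 50),
        label = paste0("p", i)
      )
    })
  })
  total <- aggregate_series(parts, paste0("p", 1:4), label = "total")
  share_sum <- Reduce(`+`, lapply(parts, function(p) {
    share_outcome(p, total)$data$volume
  }))
  expect_equal(share_sum, rep(1, 104))
})

test_that("rank deficiency and tiny samples are rejected", {
  s <- generate_interest_series(shock_params())
  spec <- default_spec()
  design <- build_design(s, spec)
  expect_error(
    fit_rdd(design[design$year == 2019, ][1:10, ], spec),
    "observations|rank"
  )
})
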