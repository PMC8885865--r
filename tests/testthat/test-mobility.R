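test_that("weekly smoothing: constants are fixed points, edges use >= 4 days", {
  dates <- seq(as.Date("2020-02-01"), by = "day", length.out = 30)
  m <- mobility_series("US", dates, rep(20, 30))
  sm <- smooth_weekly(m)
  expect_equal(sm$data$residential, rep(20, 30))
  expect_true(isTRUE(attr(sm, "smoothed")))
  # smoothing an already-constant smoothed series changes nothing
  expect_equal(smooth_weekly(sm)$data$residential, sm$data$residential)
  short <- mobility_series("US", dates[1:6], rep(1, 6))
  expect_error(smooth_weekly(short), "at least 7")
})

test_that("weekly smoothing matches the hand-computed centered means on a step", {
  dates <- seq(as.Date("2020-03-01"), by = "day", length.out = 21)
  x <- c(rep(0, 10), rep(21, 11)) # step up on day 11
  sm <- smooth_weekly(mobility_series("US", dates, x))
  # hand oracle: centered 7-day window, partial at the edges (>= 4 days)
  oracle <- sapply(seq_along(x), function(i) {
    win <- max(1, i - 3):min(length(x), i + 3)
    mean(x[win])
  })
  expect_equal(sm$data$residential, oracle)
  # explicit values around the step
  expect_equal(sm$data$residential[8], 21 / 7) # window days 5..11, one at 21
  expect_equal(sm$data$residential[11], 4 * 21 / 7) # days 8..14, four at 21
})

test_that("changepoint detection matches a brute-force scan on synthetic data", {
  p <- mobility_shock_params(
    onset_day = as.Date("2020-03-15"), peak_severity = 30,
    rise_days = 14, plateau_days = 45, recovery_days = 45,
    second_onset_day = as.Date("2020-10-05"), second_peak_severity = 18
  )
  m <- generate_mobility_series(p)
  sm <- smooth_weekly(m)
  cp <- detect_changepoints(m)
  # oracle: linear scan of the smoothed values
  x <- sm$data$residential
  d <- sm$data$date
  i1 <- which(x >= 10)[1]
  i2 <- i1 + which(x[(i1 + 1):length(x)] < 10)[1]
  i3 <- i2 + which(x[(i2 + 1):length(x)] >= 10)[1]
  expect_equal(cp$first_decrease, d[i1])
  expect_equal(cp$mobility_increase, d[i2])
  expect_equal(cp$second_decrease, d[i3])
  expect_equal(cp$peak_severity, max(x[i1:(i2 - 1)]))
})

test_that("detected onset is within 3 days of the true threshold crossing", {
  for (sev in c(15, 25, 31.6)) {
    p <- mobility_shock_params(
      onset_day = as.Date("2020-03-10"),
      peak_severity = sev, rise_days = 12
    )
    m <- generate_mobility_series(p)
    true_cross <- m$data$date[which(m$data$residential >= 10)[1]]
    cp <- detect_changepoints(m)
    expect_lte(abs(as.numeric(cp$first_decrease - true_cross)), 3)
    # noiseless plateau: severity recovered exactly
    expect_equal(cp$peak_severity, sev)
    expect_equal(peak_severity(m, cp), sev)
  }
})

test_that("series never reaching the threshold has no changepoints", {
  dates <- seq(as.Date("2020-02-01"), by = "day", length.out = 60)
  m <- mobility_series("SE", dates, rep(5, 60))
  cp <- detect_changepoints(m)
  expect_true(is.na(cp$first_decrease))
  expect_true(is.na(cp$mobility_increase))
  expect_true(is.na(cp$second_decrease))
  expect_true(is.na(cp$peak_severity))
  expect_error(peak_severity(m, cp), "no period")
})

test_that("series above threshold from the start: onset is the first date", {
  dates <- seq(as.Date("2020-02-01"), by = "day", length.out = 30)
  m <- mobility_series("IT", dates, rep(15, 30))
  cp <- detect_changepoints(m)
  expect_equal(cp$first_decrease, dates[1])
  expect_equal(cp$peak_severity, 15)
})

test_that("detection is invariant to observations after the last crossing", {
  p <- mobility_shock_params(
    onset_day = as.Date("2020-03-15"), peak_severity = 25
  )
  m_full <- generate_mobility_series(p, to = as.Date("2020-12-31"))
  m_short <- generate_mobility_series(p, to = as.Date("2020-09-30"))
  cp_full <- detect_changepoints(m_full)
  cp_short <- detect_changepoints(m_short)
  expect_equal(cp_full$first_decrease, cp_short$first_decrease)
  expect_equal(cp_full$mobility_increase, cp_short$mobility_increase)
  expect_equal(cp_full$peak_severity, cp_short$peak_severity)
})

test_that("brief sub-threshold dips are ignored with a message", {
  dates <- seq(as.Date("2020-03-01"), by = "day", length.out = 200)
  x <- rep(0, 200)
  x[30:100] <- 30
  x[60:61] <- 8 # 2-day dip, shorter than the persistence window
  m <- mobility_series("XX", dates, x)
  attr(m, "smoothed") <- TRUE # bypass smoothing to keep the dip sharp
  expect_message(cp <- detect_changepoints(m), "ignored")
  expect_equal(cp$mobility_increase, dates[101])
})

test_that("peak severity is at least the threshold whenever an onset exists", {
  for (sev in c(10.5, 12, 20)) {
    m <- generate_mobility_series(
      mobility_shock_params(peak_severity = sev, noise_sigma = 0.5, seed = 3)
    )
    cp <- detect_changepoints(m)
    if (!is.na(cp$first_decrease)) {
      expect_gte(cp$peak_severity, cp$threshold)
    }
  }
})

test_that("mobility CSV round-trips through the report dialect", {
  m <- generate_mobility_series(
    mobility_shock_params(peak_severity = 22, noise_sigma = 1, seed = 5),
    country = "BR"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_mobility_csv(list(BR = m), path)
  back <- read_mobility_csv(path)
  expect_equal(back$BR$data$residential, m$data$residential)
  expect_equal(back$BR$data$date, m$data$date)
})

test_that("sub-national rows are filtered out when reading mobility CSVs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "country_region_code,sub_region_1,date,residential_percent_change_from_baseline",
    "IT,,2020-02-01,1",
    "IT,Lombardy,2020-02-01,99",
    "IT,,2020-02-02,2"
  ), path)
  out <- read_mobility_csv(path)
  expect_equal(out$IT$data$residential, c(1, 2))
})
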