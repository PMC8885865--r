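#' Parameters of the seasonal-shock interest generator
#'
#' The generator produces two 52-week years of multiplicative weekly search
#' interest sharing one seasonal component, with an optional post-cutoff shock
#' in the treatment year. On the log scale a week `w` of year `T` has mean
#'
#'   `log(baseline_level) + trend_per_week * t + log(holiday_multiplier) * [w
#'   in holiday_weeks] + [T = treatment and t > 0] * (a + b t + g t^2)`
#'
#' where `t = w - cutoff_week_of_year` and `(a, b, g)` are
#' `shock_log_effect` and the two components of `shock_decay`. Noise is
#' lognormal: independent Normal(0, `noise_sigma`) draws are added on the log
#' scale. The post-cutoff term is a quadratic in `t`, so the generative model
#' is nested in the quadratic discontinuity regression and injected effects
#' are exactly recoverable from noiseless data.
#'
#' @param baseline_level positive baseline volume.
#' @param trend_per_week seasonal log-linear trend per week (applied
#'   identically in both years, as a function of week-of-year).
#' @param holiday_weeks integer weeks in `[1, 52]` receiving the holiday bump
#'   (both years).
#' @param holiday_multiplier multiplicative holiday bump, `>= 1`.
#' @param shock_log_effect true short-term effect on the log scale (the
#'   treatment-year discontinuity jump).
#' @param shock_decay length-2 numeric: linear and quadratic decay of the
#'   shock on the log scale, per week and per week squared.
#' @param cutoff_week_of_year week-of-year of the cutoff; the cutoff week
#'   itself is untreated.
#' @param noise_sigma standard deviation of the log-scale noise, `>= 0`.
#' @param seed integer seed; identical parameters give identical series.
#' @return a validated list of class `seasonal_shock_params`.
#' @export
seasonal_shock_params <- function(baseline_level = 100,
                                  trend_per_week = 0,
                                  holiday_weeks = c(51L, 52L),
                                  holiday_multiplier = 1.5,
                                  shock_log_effect = 0,
                                  shock_decay = c(0, 0),
                                  cutoff_week_of_year = 12L,
                                  noise_sigma = 0,
                                  seed = 1L) {
  p <- structure(
    list(
      baseline_level = baseline_level, trend_per_week = trend_per_week,
      holiday_weeks = as.integer(holiday_weeks),
      holiday_multiplier = holiday_multiplier,
      shock_log_effect = shock_log_effect,
      shock_decay = as.numeric(shock_decay),
      cutoff_week_of_year = as.integer(cutoff_week_of_year),
      noise_sigma = noise_sigma, seed = as.integer(seed)
    ),
    class = "seasonal_shock_params"
  )
  if (!is.numeric(p$baseline_level) || p$baseline_level <= 0) {
    stop("seasonal_shock_params: baseline_level must be > 0", call. = FALSE)
  }
  if (p$noise_sigma < 0) {
    stop("seasonal_shock_params: noise_sigma must be >= 0", call. = FALSE)
  }
  if (length(p$holiday_weeks) &&
    any(p$holiday_weeks < 1L | p$holiday_weeks > 52L)) {
    stop("seasonal_shock_params: holiday_weeks must lie in [1, 52]",
      call. = FALSE
    )
  }
  if (p$holiday_multiplier < 1) {
    stop("seasonal_shock_params: holiday_multiplier must be >= 1",
      call. = FALSE
    )
  }
  if (length(p$shock_decay) != 2L) {
    stop("seasonal_shock_params: shock_decay must have length 2", call. = FALSE)
  }
  if (p$cutoff_week_of_year < 1L || p$cutoff_week_of_year > 52L) {
    stop("seasonal_shock_params: cutoff_week_of_year must lie in [1, 52]",
      call. = FALSE
    )
  }
  p
}

#' Generate a synthetic weekly interest series
#'
#' Produces 104 weekly observations (weeks 1--52 of a baseline year and a
#' treatment year) from the seasonal-shock model described in
#' [seasonal_shock_params()]. The two years share the seasonal component
#' exactly; only post-cutoff weeks of the treatment year receive the shock.
#'
#' @param params a [seasonal_shock_params()] object.
#' @param country,label labels attached to the series.
#' @param years length-2 integer vector `(baseline, treatment)` used to label
#'   the two years.
#' @return an [interest_series()].
#' @examples
#' p <- seasonal_shock_params(shock_log_effect = log(2), noise_sigma = 0)
#' s <- generate_interest_series(p)
#' # post-cutoff 2020 weeks are exactly twice their 2019 counterparts
#' d <- s$data
#' all.equal(
#'   d$volume[d$year == 2020 & d$week > 12],
#'   2 * d$volume[d$year == 2019 & d$week > 12]
#' )
#' @export
generate_interest_series <- function(params, country = "SY",
                                     label = "synthetic",
                                     years = c(2019L, 2020L)) {
  stopifnot(inherits(params, "seasonal_shock_params"), length(years) == 2L)
  weeks <- 1:52
  t_rel <- weeks - params$cutoff_week_of_year
  seasonal <- log(params$baseline_level) +
    params$trend_per_week * t_rel +
    log(params$holiday_multiplier) * (weeks %in% params$holiday_weeks)
  shock <- ifelse(
    t_rel > 0,
    params$shock_log_effect +
      params$shock_decay[1] * t_rel +
      params$shock_decay[2] * t_rel^2,
    0
  )
  log_mu <- c(seasonal, seasonal + shock)
  noise <- withr::with_seed(
    params$seed,
    rnorm(104L, mean = 0, sd = params$noise_sigma)
  )
  interest_series(
    country = country, label = label,
    year = rep(years, each = 52L), week = rep(weeks, 2L),
    volume = exp(log_mu + noise)
  )
}

#' Parameters of the lockdown mobility generator
#'
#' The generator emulates a daily residential-mobility series on Google's
#' percent-change-from-baseline scale: zero before lockdown onset, a smooth
#' monotone rise over `rise_days` to `peak_severity`, a plateau, a monotone
#' recovery back to zero, and an optional second wave that rises to
#' `second_peak_severity` and persists to the end of the year. Gaussian noise
#' with standard deviation `noise_sigma` is added daily.
#'
#' @param onset_day `Date`; first day of the rise.
#' @param peak_severity peak percent increase in time at home, `>= 0`.
#' @param rise_days,plateau_days,recovery_days segment lengths in days
#'   (`rise_days`, `recovery_days` > 0; `plateau_days` >= 0).
#' @param second_onset_day optional `Date`; must fall after the first wave has
#'   fully recovered.
#' @param second_peak_severity percent; required with `second_onset_day`.
#' @param noise_sigma daily Gaussian noise SD in percent, `>= 0`.
#' @param seed integer seed.
#' @return a validated list of class `mobility_shock_params`.
#' @export
mobility_shock_params <- function(onset_day = as.Date("2020-03-15"),
                                  peak_severity = 25,
                                  rise_days = 14L,
                                  plateau_days = 45L,
                                  recovery_days = 60L,
                                  second_onset_day = NULL,
                                  second_peak_severity = NULL,
                                  noise_sigma = 0,
                                  seed = 1L) {
  p <- structure(
    list(
      onset_day = as.Date(onset_day), peak_severity = peak_severity,
      rise_days = as.integer(rise_days),
      plateau_days = as.integer(plateau_days),
      recovery_days = as.integer(recovery_days),
      second_onset_day = if (!is.null(second_onset_day)) {
        as.Date(second_onset_day)
      },
      second_peak_severity = second_peak_severity,
      noise_sigma = noise_sigma, seed = as.integer(seed)
    ),
    class = "mobility_shock_params"
  )
  if (p$peak_severity < 0) {
    stop("mobility_shock_params: peak_severity must be >= 0", call. = FALSE)
  }
  if (p$rise_days <= 0L || p$recovery_days <= 0L || p$plateau_days < 0L) {
    stop("mobility_shock_params: invalid segment lengths", call. = FALSE)
  }
  if (p$noise_sigma < 0) {
    stop("mobility_shock_params: noise_sigma must be >= 0", call. = FALSE)
  }
  if (!is.null(p$second_onset_day)) {
    if (is.null(p$second_peak_severity)) {
      stop("mobility_shock_params: second wave needs second_peak_severity",
        call. = FALSE
      )
    }
    first_end <- p$onset_day + p$rise_days + p$plateau_days + p$recovery_days
    if (p$second_onset_day <= first_end) {
      stop("mobility_shock_params: second wave overlaps the first wave",
        call. = FALSE
      )
    }
  }
  p
}

# raised-cosine ramp: exact 0 at u = 0, exact 1 at u = 1, strictly monotone
.ramp <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

#' Generate a synthetic daily mobility series
#'
#' @param params a [mobility_shock_params()] object.
#' @param country label attached to the series.
#' @param from,to span of the daily grid (defaults: February 1 to
#'   December 31, 2020, the span of the published mobility reports).
#' @return a [mobility_series()].
#' @examples
#' m <- generate_mobility_series(mobility_shock_params(peak_severity = 30))
#' max(m$data$residential) # exactly 30 in the noiseless case
#' @export
generate_mobility_series <- function(params, country = "SY",
                                     from = as.Date("2020-02-01"),
                                     to = as.Date("2020-12-31")) {
  stopifnot(inherits(params, "mobility_shock_params"))
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  base <- mobility_curve(params, dates)
  noise <- withr::with_seed(
    params$seed,
    rnorm(length(dates), 0, params$noise_sigma)
  )
  mobility_series(country, dates, base + noise)
}

# noiseless piecewise curve; used both by the generator and as the
# ground-truth oracle in tests
mobility_curve <- function(params, dates) {
  d <- as.numeric(dates - params$onset_day) # days since onset
  r <- params$rise_days
  pl <- params$plateau_days
  rec <- params$recovery_days
  v <- numeric(length(d))
  rising <- d > 0 & d <= r
  v[rising] <- params$peak_severity * .ramp(d[rising] / r)
  v[d > r & d <= r + pl] <- params$peak_severity
  falling <- d > r + pl & d <= r + pl + rec
  v[falling] <- params$peak_severity * (1 - .ramp((d[falling] - r - pl) / rec))
  if (!is.null(params$second_onset_day)) {
    d2 <- as.numeric(dates - params$second_onset_day)
    rising2 <- d2 > 0 & d2 <= r
    v[rising2] <- params$second_peak_severity * .ramp(d2[rising2] / r)
    v[d2 > r] <- params$second_peak_severity
  }
  v
}

#' Generate a multi-country panel with known dose-response ground truth
#'
#' Builds `n_countries` synthetic countries whose lockdown severities are
#' evenly spread over `severity_range` and whose true log-scale short-term
#' effects follow the linear coupling
#' `alpha = dose_slope * severity / 100 + Normal(0, alpha_noise_sd)`.
#' Each country gets one interest series per requested group and one mobility
#' series whose noiseless peak equals its severity; the generating truth is
#' recorded so downstream estimates can be checked against it.
#'
#' @param n_countries integer `>= 3`.
#' @param severity_range length-2 numeric, percent; must have positive width
#'   when `n_countries > 1`.
#' @param dose_slope linear coupling of severity (as a fraction) to the true
#'   log-scale effect.
#' @param seed integer seed driving all randomness.
#' @param groups character vector of group labels to generate per country.
#' @param alpha_noise_sd SD of country-level noise on the true effect.
#' @param noise_sigma log-scale weekly noise SD of the interest series.
#' @param mobility_noise_sigma daily noise SD of the mobility series.
#' @param shock_decay decay `(b, g)` shared by all countries.
#' @return a list of class `synthetic_panel` with elements `countries`,
#'   `interest` (country -> group -> [interest_series()]), `mobility`
#'   (country -> [mobility_series()]), `truth` (tibble with `country`,
#'   `severity`, `alpha`, `onset_day`, `cutoff_week`) and `dose_slope`.
#' @export
generate_country_panel <- function(n_countries,
                                   severity_range = c(10.1, 31.6),
                                   dose_slope = 2,
                                   seed = 1L,
                                   groups = "total_food",
                                   alpha_noise_sd = 0,
                                   noise_sigma = 0,
                                   mobility_noise_sigma = 0,
                                   shock_decay = c(0, 0)) {
  if (n_countries < 3L) {
    stop("generate_country_panel: n_countries must be >= 3", call. = FALSE)
  }
  stopifnot(length(severity_range) == 2L)
  if (diff(range(severity_range)) == 0 && n_countries > 1L) {
    stop("generate_country_panel: degenerate severity_range", call. = FALSE)
  }
  countries <- sprintf("C%02d", seq_len(n_countries))
  severities <- seq(severity_range[1], severity_range[2],
    length.out = n_countries
  )
  alpha_noise <- withr::with_seed(
    seed,
    rnorm(n_countries, 0, alpha_noise_sd)
  )
  alphas <- dose_slope * severities / 100 + alpha_noise
  # onsets staggered over mid/late March so the cutoff week stays >= 11
  onsets <- as.Date("2020-03-12") + (seq_len(n_countries) - 1L) %% 14L

  interest <- list()
  mobility <- list()
  cutoff_weeks <- integer(n_countries)
  for (i in seq_len(n_countries)) {
    cc <- countries[i]
    # the interest shock starts at the week of the detected mobility
    # decrease: locate the (noiseless, smoothed) threshold crossing so the
    # generated data is internally consistent with the study design
    mob_params <- mobility_shock_params(
      onset_day = onsets[i], peak_severity = severities[i],
      noise_sigma = mobility_noise_sigma, seed = seed + 500000L + i
    )
    noiseless <- mobility_series(
      cc, seq(as.Date("2020-02-01"), as.Date("2020-12-31"), by = "day"),
      mobility_curve(
        mob_params,
        seq(as.Date("2020-02-01"), as.Date("2020-12-31"), by = "day")
      )
    )
    cp <- detect_changepoints(noiseless)
    cutoff <- week_of_year(cp$first_decrease)
    cutoff_weeks[i] <- cutoff
    interest[[cc]] <- lapply(setNames(groups, groups), function(g) {
      generate_interest_series(
        seasonal_shock_params(
          shock_log_effect = alphas[i],
          shock_decay = shock_decay,
          cutoff_week_of_year = cutoff,
          noise_sigma = noise_sigma,
          seed = seed + 1000L * i + match(g, groups)
        ),
        country = cc, label = g
      )
    })
    mobility[[cc]] <- generate_mobility_series(mob_params, country = cc)
  }
  structure(
    list(
      countries = countries,
      interest = interest,
      mobility = mobility,
      truth = tibble::tibble(
        country = countries, severity = severities,
        alpha = alphas, onset_day = onsets, cutoff_week = cutoff_weeks
      ),
      dose_slope = dose_slope
    ),
    class = "synthetic_panel"
  )
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(
    "<synthetic_panel> ", length(x$countries), " countries, ",
    length(x$interest[[1]]), " interest group(s) each; dose_slope = ",
    x$dose_slope, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic study (interest, catalog-ready entities, mobility) to CSV
#'
#' Materialises a per-entity interest panel and a mobility file in exactly the
#' CSV schemas the pipeline reads, so generated data is a drop-in replacement
#' for deposited study data. Every entity of the catalog receives its own
#' series; all entities of a country share that country's shock, so group
#' aggregates inherit the known truth.
#'
#' @param catalog an [load_catalog()] catalog (or path to one).
#' @param dir output directory (created if needed).
#' @param n_countries,severity_range,dose_slope,seed,alpha_noise_sd,noise_sigma
#'   passed to [generate_country_panel()]-style generation.
#' @return invisibly, a list with `interest_path`, `mobility_path` and the
#'   ground-truth tibble.
#' @export
simulate_study_inputs <- function(catalog, dir,
                                  n_countries = 3L,
                                  severity_range = c(12, 30),
                                  dose_slope = 2,
                                  seed = 1L,
                                  alpha_noise_sd = 0,
                                  noise_sigma = 0.05) {
  if (is.character(catalog)) catalog <- load_catalog(catalog)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- catalog$entries$entity_id
  panel <- generate_country_panel(
    n_countries = n_countries, severity_range = severity_range,
    dose_slope = dose_slope, seed = seed, groups = ids,
    alpha_noise_sd = alpha_noise_sd, noise_sigma = noise_sigma
  )
  series <- unlist(unname(panel$interest), recursive = FALSE)
  interest_path <- file.path(dir, "interest_panel.csv")
  mobility_path <- file.path(dir, "mobility.csv")
  write_interest_panel(series, interest_path)
  write_mobility_csv(panel$mobility, mobility_path)
  invisible(list(
    interest_path = interest_path, mobility_path = mobility_path,
    truth = panel$truth, countries = panel$countries
  ))
}
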