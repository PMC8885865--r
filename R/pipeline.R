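#' Read and write per-entity interest panels
#'
#' The panel CSV has columns `country`, `entity_id`, `year`, `week`,
#' `volume`. Week-53 rows (from 53-week ISO years) are dropped with a
#' message; negative volumes and unparseable rows are hard errors. Writing
#' uses a round-trip-exact decimal representation, so a written panel reads
#' back bit-identical.
#'
#' @param path CSV file path.
#' @return `read_interest_panel()`: a named list of [interest_series()],
#'   keyed `"<country>:<entity_id>"`.
#' @export
read_interest_panel <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      entity_id = readr::col_character(),
      year = readr::col_integer(),
      week = readr::col_integer(),
      # parsed via base strtod below for exact decimal -> binary round-trips
      volume = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop("read_interest_panel: unparseable row(s) at line(s) ",
      paste(utils::head(probs$row, 5), collapse = ", "),
      call. = FALSE
    )
  }
  need <- c("country", "entity_id", "year", "week", "volume")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_interest_panel: missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  vol <- as.numeric(df$volume)
  if (anyNA(vol) & !anyNA(df$volume)) {
    stop("read_interest_panel: unparseable volume value(s)", call. = FALSE)
  }
  df$volume <- vol
  if (any(df$volume < 0)) {
    stop("read_interest_panel: negative volume(s)", call. = FALSE)
  }
  w53 <- df$week == 53L
  if (any(w53)) {
    message("read_interest_panel: dropped ", sum(w53), " week-53 row(s)")
    df <- df[!w53, ]
  }
  key <- paste(df$country, df$entity_id, sep = ":")
  lapply(split(df, key), function(g) {
    interest_series(g$country[1], g$entity_id[1], g$year, g$week, g$volume)
  })
}

#' @rdname read_interest_panel
#' @param series list of [interest_series()] (labels are written as
#'   `entity_id`).
#' @export
write_interest_panel <- function(series, path) {
  rows <- lapply(series, function(s) {
    tibble::tibble(
      country = s$country, entity_id = s$label,
      year = s$data$year, week = s$data$week,
      # 17 significant digits: doubles survive the round-trip bit-exactly
      volume = sprintf("%.17g", s$data$volume)
    )
  })
  readr::write_csv(do.call(rbind, rows), path, progress = FALSE)
  invisible(path)
}

#' Configuration of a full study run
#'
#' @param interest_path per-entity interest panel CSV
#'   ([read_interest_panel()] schema).
#' @param catalog_path entity catalog CSV ([load_catalog()] schema).
#' @param mobility_path mobility CSV ([read_mobility_csv()] schema).
#' @param out_dir output directory for result tables and the manifest.
#' @param countries country codes to analyse (default: all present in the
#'   interest panel).
#' @param t_min,t_max bandwidth of the discontinuity model (defaults 10, 30).
#' @param correlation_window treatment-year weeks of the mobility--interest
#'   correlation (default `6:51`).
#' @param dose_exclude countries excluded from dose-response fits.
#' @param threshold mobility threshold in percent (default 10).
#' @param seed integer recorded in the manifest (the study itself is
#'   deterministic given its inputs).
#' @return a list of class `run_config`.
#' @export
run_config <- function(interest_path, catalog_path, mobility_path, out_dir,
                       countries = NULL, t_min = 10L, t_max = 30L,
                       correlation_window = 6:51,
                       dose_exclude = character(),
                       threshold = 10, seed = 1L) {
  for (p in c(interest_path, catalog_path, mobility_path)) {
    if (!file.exists(p)) stop("run_config: no such file: ", p, call. = FALSE)
  }
  structure(
    list(
      interest_path = interest_path, catalog_path = catalog_path,
      mobility_path = mobility_path, out_dir = out_dir,
      countries = countries, t_min = as.integer(t_min),
      t_max = as.integer(t_max),
      correlation_window = as.integer(correlation_window),
      dose_exclude = dose_exclude, threshold = threshold,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# fit one series through all three forms plus derived quantities;
# returns a list of result rows (tibbles) or signals an error
fit_series_record <- function(s, cutoff_week, t_min, t_max, country, group,
                              outcome = "log_volume", wave = "first") {
  out <- list()
  for (form in c("quadratic", "linear", "constant")) {
    spec <- model_spec(
      cutoff_week = cutoff_week, form = form,
      t_min = t_min, t_max = t_max, outcome = outcome
    )
    design <- build_design(s, spec)
    fit <- fit_rdd(design, spec)
    eff <- short_term_effect(fit)
    row <- tibble::tibble(
      country = country, group = group, outcome = outcome, wave = wave,
      form = form, cutoff_week = cutoff_week, n_obs = fit$n_obs,
      alpha = eff$log_point, alpha_se = eff$log_se,
      effect = eff$point, effect_ci_low = eff$ci_low,
      effect_ci_high = eff$ci_high, effect_p = eff$p_value,
      significant = eff$significant,
      reversion_status = NA_character_, reversion_weeks = NA_integer_,
      long_term_effect = NA_real_, long_term_p = NA_real_
    )
    if (form == "quadratic") {
      rev <- reversion_time(fit)
      lte <- long_term_effect(fit)
      row$reversion_status <- rev$status
      row$reversion_weeks <- rev$weeks
      row$long_term_effect <- lte$point
      row$long_term_p <- lte$p_value
    }
    out[[form]] <- row
  }
  do.call(rbind, out)
}

#' Run the full study on an input bundle
#'
#' End-to-end orchestration: reads the catalog, interest panel and mobility
#' series; detects changepoints and severity per country; aggregates entities
#' into food categories, the four access modes and total food; fits the
#' discontinuity model (all three forms) per country and group with the
#' short-term effect, reversion time and long-term effect; fits the
#' share-of-interest variant for food categories; computes
#' mobility--interest correlations and the cross-country dose-response;
#' produces the surplus-of-interest report; and re-runs the model at the
#' second-wave cutoff where one is detected. Per-series failures (e.g. zero
#' volumes inside the window) abort only that series and are recorded in the
#' manifest.
#'
#' All tables are written as CSV under `config$out_dir` along with
#' `manifest.json` capturing the configuration, seed and per-series outcome
#' counts. The run is fully deterministic given `(config, inputs)`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `fits`, `changepoints`, `correlations`,
#'   `dose_response`, `surplus`, `failures` and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  catalog <- load_catalog(config$catalog_path)
  panel <- read_interest_panel(config$interest_path)
  mobility <- read_mobility_csv(config$mobility_path)

  panel_countries <- unique(vapply(panel, function(s) s$country, character(1)))
  countries <- if (is.null(config$countries)) {
    sort(panel_countries)
  } else {
    config$countries
  }
  if (length(countries) == 0L) {
    stop("run_study: no countries to analyse", call. = FALSE)
  }

  cat_members <- food_category_members(catalog)
  am_members <- access_mode_members(catalog)
  food_ids <- catalog$entries$entity_id[catalog$entries$kind == "food"]
  groups <- c(
    cat_members, am_members,
    list(total_food = food_ids)
  )
  food_cats <- names(cat_members)

  failures <- list()
  note_failure <- function(country, group, stage, msg) {
    failures[[length(failures) + 1L]] <<- tibble::tibble(
      country = country, group = group, stage = stage, message = msg
    )
  }

  fit_rows <- list()
  cp_rows <- list()
  cor_rows <- list()
  surplus_rows <- list()
  planned <- 0L
  done <- 0L

  for (cc in countries) {
    if (is.null(mobility[[cc]])) {
      note_failure(cc, NA_character_, "mobility", "no mobility series")
      next
    }
    sm <- smooth_weekly(mobility[[cc]])
    cp <- detect_changepoints(sm, threshold = config$threshold)
    cp_rows[[cc]] <- tibble::tibble(
      country = cc,
      first_decrease = cp$first_decrease,
      mobility_increase = cp$mobility_increase,
      second_decrease = cp$second_decrease,
      peak_severity = cp$peak_severity,
      threshold = cp$threshold
    )
    if (is.na(cp$first_decrease)) {
      note_failure(cc, NA_character_, "changepoints", "no mobility decrease")
      next
    }
    cutoff <- week_of_year(cp$first_decrease)

    entity_series <- panel[vapply(
      panel, function(s) s$country == cc, logical(1)
    )]
    agg <- function(members, label) {
      aggregate_series(entity_series, members, label)
    }
    total <- tryCatch(agg(food_ids, "total_food"), error = function(e) NULL)

    for (g in names(groups)) {
      planned <- planned + 1L
      res <- tryCatch(
        {
          s <- agg(groups[[g]], g)
          fit_series_record(
            s, cutoff, config$t_min, config$t_max, cc, g
          )
        },
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        note_failure(cc, g, "fit", res)
      } else {
        done <- done + 1L
        fit_rows[[paste(cc, g)]] <- res
      }

      # share-of-interest variant for food categories
      if (g %in% food_cats && !is.null(total)) {
        share_res <- tryCatch(
          {
            sh <- share_outcome(agg(groups[[g]], g), total)
            fit_series_record(
              sh, cutoff, config$t_min, config$t_max, cc, g,
              outcome = "log_share"
            )
          },
          error = function(e) conditionMessage(e)
        )
        if (is.character(share_res)) {
          note_failure(cc, g, "share_fit", share_res)
        } else {
          fit_rows[[paste(cc, g, "share")]] <- share_res
        }
      }

      # correlation with mobility
      cor_res <- tryCatch(
        {
          s <- agg(groups[[g]], g)
          r <- mobility_interest_correlation(
            s, mobility[[cc]],
            window = config$correlation_window
          )
          tibble::tibble(
            country = cc, group = g, rho = r$rho, p_value = r$p_value,
            n = r$n
          )
        },
        error = function(e) conditionMessage(e)
      )
      if (is.character(cor_res)) {
        note_failure(cc, g, "correlation", cor_res)
      } else {
        cor_rows[[paste(cc, g)]] <- cor_res
      }
    }

    # second-wave rerun at the second cutoff (quadratic only), truncated so
    # the window stays on the 52-week grid
    if (!is.na(cp$second_decrease)) {
      cutoff2 <- week_of_year(cp$second_decrease)
      t_max2 <- min(config$t_max, 52L - cutoff2)
      if (t_max2 >= 3L) {
        for (g in names(groups)) {
          res2 <- tryCatch(
            {
              s <- agg(groups[[g]], g)
              fit_series_record(
                s, cutoff2, config$t_min, t_max2, cc, g,
                wave = "second"
              )
            },
            error = function(e) conditionMessage(e)
          )
          if (is.character(res2)) {
            note_failure(cc, g, "second_wave", res2)
          } else {
            fit_rows[[paste(cc, g, "w2")]] <- res2
          }
        }
      }
    }

    # surplus-of-interest report on total food
    sr <- tryCatch(
      {
        z <- zscore_series(total)
        xmas <- c(2019L, holiday_week("christmas"))
        z20 <- z$data[z$data$year == 2020L, ]
        peak_week <- z20$week[which.max(z20$z)]
        tibble::tibble(
          country = cc,
          peak_week_2020 = peak_week,
          peak_z = max(z20$z),
          christmas_week = xmas[2],
          peak_ratio = surplus_ratio(z, c(2020L, peak_week), xmas),
          h1_cumulative_ratio =
            cumulative_surplus_ratio(z, 1:26, xmas)
        )
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(sr)) {
      note_failure(cc, "total_food", "surplus", sr)
    } else {
      surplus_rows[[cc]] <- sr
    }
  }

  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
  if (is.null(fits)) stop("run_study: empty result set", call. = FALSE)

  # dose-response: severity vs log-scale short-term effect, per access mode
  cps <- do.call(rbind, cp_rows)
  severity <- setNames(cps$peak_severity, cps$country)
  severity <- severity[!is.na(severity)]
  dr_rows <- list()
  for (g in names(am_members)) {
    sel <- fits[fits$group == g & fits$form == "quadratic" &
      fits$outcome == "log_volume" & fits$wave == "first", ]
    if (nrow(sel) >= 3L) {
      alphas <- setNames(sel$alpha, sel$country)
      dr <- tryCatch(
        dose_response(severity, alphas, exclude = config$dose_exclude),
        error = function(e) NULL
      )
      if (!is.null(dr)) {
        dr_rows[[g]] <- tibble::tibble(
          group = g, pearson_r = dr$pearson_r, p_value = dr$p_value,
          slope = dr$slope, intercept = dr$intercept, n = dr$n,
          excluded = paste(dr$excluded, collapse = ";")
        )
      }
    }
  }

  results <- list(
    fits = fits,
    changepoints = cps,
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL,
    dose_response = if (length(dr_rows)) do.call(rbind, dr_rows) else NULL,
    surplus = if (length(surplus_rows)) {
      do.call(rbind, surplus_rows)
    } else {
      NULL
    },
    failures = if (length(failures)) do.call(rbind, failures) else NULL
  )

  manifest <- list(
    config = config[c(
      "interest_path", "catalog_path", "mobility_path", "countries",
      "t_min", "t_max", "correlation_window", "dose_exclude", "threshold",
      "seed"
    )],
    planned_primary_fits = planned,
    completed_primary_fits = done,
    failed_primary_fits = planned - done,
    n_failures_recorded = length(failures),
    groups = names(groups),
    countries = countries
  )
  results$manifest <- manifest

  for (nm in c(
    "fits", "changepoints", "correlations", "dose_response",
    "surplus", "failures"
  )) {
    if (!is.null(results[[nm]])) {
      readr::write_csv(
        results[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
        progress = FALSE
      )
    }
  }
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", Date = "ISO8601"
  )
  invisible(results)
}
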