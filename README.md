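# dietshift

Population-scale shifts in dietary interest under mobility restrictions,
measured from calibrated weekly search-volume panels.

When lockdowns confined people to their homes in 2020, what they looked for
changed: more recipes, baking and bread; fewer restaurants. `dietshift` is an
R toolkit for quantifying such shifts from two passively sensed signals:

* **weekly search-interest series** per food entity and country, calibrated so
  that series share one multiplicative scale and can be summed into food
  categories and food-access modes (at home / outside x household / third
  party); and
* **daily residential-mobility series** — the percent change in time spent at
  home relative to a pre-pandemic baseline.

It is written for epidemiologists and computational social scientists who
want the full analysis — changepoints, effect estimation, reversion times,
surplus metrics, correlations, dose-response — as tested, reusable functions
rather than a one-off notebook, plus a synthetic-data generator with known
ground truth so every stage can be validated offline.

## The model

The onset of reduced mobility in a country is detected from the smoothed
(7-day centered rolling mean) residential series as the first day it reaches
+10%. With the cutoff placed at that week, each interest series is modeled by
a **difference-in-discontinuities regression**: a regression discontinuity
design in the treatment year, minus a "fake" discontinuity at the same weeks
of the control year to remove seasonality,

```
log y_tT = α′ + β′·t + γ′·t²                      (baseline trend)
         + α″·i_t + β″·i_t·t + γ″·i_t·t²          (post-cutoff trend, both years)
         + α‴·j_T + β‴·j_T·t + γ‴·j_T·t²          (treatment-year offset)
         + α·i_t·j_T + β·i_t·j_T·t + γ·i_t·j_T·t² (the effect of the shock)
```

where `t ∈ [−10, 30]` is the week relative to the cutoff, `i_t = 1` for
`t > 0`, and `j_T = 1` in the treatment year (82 weekly observations per
fit). The log outcome makes the model multiplicative. Three quantities are
derived from the interaction block:

* **short-term effect** `e^α − 1`, the jump in interest at the cutoff, with a
  95% CI from `α ± 2·SE`;
* **reversion time**: the first week from which the fitted treatment-year
  curve and the control-year counterfactual have overlapping 95% intervals
  through the end of the window;
* **long-term effect**: how elevated the fit remains at `t = 30`, as
  `e^contrast − 1`.

Around the model sit the surplus-of-interest metrics (weekly z-scores
relative to the control-year mean and SD, compared against the Christmas
reference week), seasonality-adjusted Spearman correlations between weekly
mobility and year-over-year interest change, and the cross-country
dose-response of lockdown severity (peak smoothed mobility) against the
estimated effects.

## Worked example

Generate a synthetic series with a known injected shock (+60% at the cutoff,
decaying over the window), fit the model, and read off the three quantities:

```r
library(dietshift)

p <- seasonal_shock_params(
  baseline_level = 100, shock_log_effect = log(1.6),
  shock_decay = c(-0.03, 4e-4), noise_sigma = 0.08, seed = 42
)
s <- generate_interest_series(p, country = "BR", label = "pastry_and_bakery")

spec <- model_spec(cutoff_week = 12)
fit  <- fit_rdd(build_design(s, spec), spec)
fit
#> <rdd_fit> form = quadratic, n = 82, cutoff week 12
#>   shock jump alpha = 0.6416 (SE 0.1070) -> short-term effect +90.0%

short_term_effect(fit)
#> <effect_estimate> +90.0% [+53.4%, +135.3%], p = 7.86e-08 *
reversion_time(fit)
#> <reversion_time> reverted after 17 weeks
long_term_effect(fit)
#> <effect_estimate> +6.5% [-5.0%, +19.4%], p = 0.272
```

The fitted jump (here +90%) estimates the injected shock net of its decay and
the noise realisation; the interest reverts to the seasonal counterfactual
after 17 weeks, and by week 30 no significant elevation remains. Mobility
changepoints and the seasonality-adjusted association work the same way:

```r
m  <- generate_mobility_series(
  mobility_shock_params(onset_day = as.Date("2020-03-12"), peak_severity = 28),
  country = "BR"
)
detect_changepoints(m)
#> <changepoint_set> [BR] onset: 2020-03-18, relaxation: 2020-06-15,
#>   second onset: -, peak severity: 28.0% (threshold 10%)

mobility_interest_correlation(s, m)
#> <spearman_result> rho = 0.707, p = 3.98e-08, n = 46
```

The end-to-end study — catalog loading, group aggregation, per-country
changepoints, fits in all three model forms, the share-of-interest variant,
correlations, dose-response, surplus report and second-wave rerun — is
orchestrated by `run_study(run_config(...))`, which writes CSV tables and a
JSON manifest. `simulate_study_inputs()` writes a complete synthetic input
bundle in the same schemas.

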