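---
title: "Measuring dietary-interest shifts: model, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dietary-interest shifts: model, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## The problem

Search volumes are a population-scale sensor for dietary interest, but the
raw weekly series mix the signal of interest — the response to an abrupt
mobility restriction — with strong seasonality (end-of-year holiday peaks),
secular trends, and an unknown multiplicative calibration factor. This
package isolates the mobility-shock response with a quasi-experimental
design and provides the surrounding measurement machinery: changepoint
detection on mobility, surplus-of-interest metrics, seasonality-adjusted
correlations, and cross-country dose-response summaries.

## The difference-in-discontinuities model

For a weekly interest series $y_{tT}$ ($t$ the week relative to the cutoff,
$T$ the year) we fit by OLS

$$\log y_{tT} = \alpha' + \beta' t + \gamma' t^2
 + \alpha'' i_t + \beta'' i_t t + \gamma'' i_t t^2
 + \alpha''' j_T + \beta''' j_T t + \gamma''' j_T t^2
 + \alpha\, i_t j_T + \beta\, i_t j_T t + \gamma\, i_t j_T t^2$$

with $i_t = \mathbf{1}[t > 0]$ and $j_T = \mathbf{1}[T = 2020]$. The
identifying idea is a discontinuity *difference*: the treatment year has a
real discontinuity at the cutoff, the control year gets a fake one at the
same week-of-year, and the interaction block $(\alpha, \beta, \gamma)$
captures only what is special about the post-cutoff treatment-year weeks —
seasonal patterns common to both years cancel. The log link makes the model
multiplicative, so $e^\alpha - 1$ is the relative jump in interest at the
cutoff and is invariant to the unknown calibration constant.

Assumptions worth stating plainly:

* within the $[-t_{\min}, t_{\max}]$ window, baseline and post-cutoff
  dynamics are adequately described by quadratics in $t$;
* errors are homoskedastic on the log scale (classical OLS standard errors;
  intervals are $\pm 2\,\mathrm{SE}$, p-values from a two-sided $t$-test
  with $n - p$ degrees of freedom);
* the control year is a valid seasonal counterfactual — nothing else
  happened at the same weeks of the control year.

No causal identification beyond these is claimed; the dose-response
analysis (below) is supporting evidence, not proof.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `t_min` | 10 | weeks | largest pre-cutoff bandwidth available when cutoffs fall in March of a 52-week year |
| `t_max` | 30 | weeks | largest window that keeps second-wave shocks out of every country's fit |
| `form` | quadratic | — | expressive enough for the rise-and-decay patterns; `linear` and `constant` are sensitivity variants |
| `threshold` | 10 | percent | level of the smoothed residential series defining reduced mobility |
| smoothing window | 7 | days | weekly rolling average removing the weekday cycle |

With the defaults a fit uses $(10 + 30 + 1) \times 2 = 82$ weekly
observations.

### Derived quantities

* **Short-term effect**: $e^{\hat\alpha} - 1$ with CI
  $e^{\hat\alpha \pm 2\mathrm{SE}} - 1$.
* **Reversion time**: the smallest $t$ from which the $\pm 2\,\mathrm{SE}$
  mean-response bands of the treatment-year fit and the control-year
  counterfactual overlap at $t$ and all later weeks of the window
  (*sustained* overlap). Requiring persistence prevents a single-week
  flicker of overlap from being declared a reversion; when the
  first-overlap and sustained-overlap answers differ, a message reports
  both. `never_differed` and `not_reverted` are distinct outcomes.
  We use pointwise mean-response intervals, not prediction intervals: the
  question is whether the *modeled mean* differs, not whether single weeks
  are predictable.
* **Long-term effect**: $e^{c'\hat\theta} - 1$ where $c$ contrasts the two
  fitted mean log outcomes at $t_{\max}$, with variance $c' \Sigma c$ from
  the coefficient covariance.

### Numerical choices

The fit itself is ordinary `lm` on an explicitly constructed design matrix;
the coefficient covariance is computed as
$\hat\sigma^2 (X'X)^{-1}$ directly, which is well defined even for
noiseless (zero-residual) inputs where `summary.lm` would warn. Rank
deficiency and windows that leave the 52-week grid are hard errors, as are
missing weeks inside the window — silent imputation would bias the
polynomial terms asymmetrically. Degenerate zero-SE cases define the
p-value as 0 for a nonzero estimate and 1 for a zero estimate.

## Week grid and reference weeks

All interest data live on a fixed 52-week grid: week $w$ covers days
$7(w-1)+1$ to $7w$ of the year, with the last one or two days folded into
week 52; week 53 never occurs (readers drop week-53 rows with a logged
count). The control-year counterpart of a treatment-year week is the same
week-of-year index. The Christmas reference week is the grid week containing
December 25 (week 52) and the Thanksgiving week the grid week containing the
fourth Thursday of November (week 48 in 2019); the "first half of 2020" is
weeks 1–26, the closest half-year expressible on a weekly grid.

The cumulative surplus-of-interest ratio sums *signed* weekly z-scores over
its window before dividing by the reference-week z-score. We read "total
surplus" as a net quantity; weeks below the baseline mean subtract. This
also makes the measure additive over disjoint windows, which the tests
exploit.

## Mobility changepoints

The raw daily series is smoothed with a centered 7-day rolling mean (edge
days use the available part of the window, at least 4 days). A centered
window was chosen over a trailing one because it biases the detected onset
symmetrically rather than systematically late. The onset of reduced
mobility is the first day the smoothed series reaches the threshold; the
relaxation is the first later day it stays below the threshold for at least
3 consecutive days (shorter dips are noise and are ignored with a message);
a second-wave onset is detected the same way after the relaxation. Lockdown
severity is the maximum of the smoothed series over the reduced-mobility
period. The threshold is read as an absolute level of the percent-change
series (+10 on the published scale), not a change relative to the series'
own start. Short reduced-mobility periods are retained — a lenient-lockdown
country is a legitimate contrasting case, not an outlier to drop.

The changepoint date is mapped to the week-of-year containing it; that week
is $t = 0$ and is itself untreated (only $t > 0$ is post-cutoff).

## Associations

The seasonality-adjusted association between mobility and interest
correlates, across treatment-year weeks, the weekly mean mobility with the
year-over-year relative change in interest. Spearman rank correlation
(average ranks for ties) is used, with the two-sided $t$-test
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; the default window, weeks 6–51, is the
46-week span from the first full week of February through December, the
period mobility reports cover. No multiple-comparison adjustment is applied
anywhere; consumers of the result tables see every test that was run.

The dose-response analysis correlates lockdown severity with the estimated
short-term effects across countries (Pearson, two-sided $t$-test, least
squares line). Exclusions are explicit, caller-supplied country lists that
are always echoed in the result — never an automatic outlier rule. By
default the correlation is computed against the log-scale jump
$\hat\alpha$ rather than $e^{\hat\alpha} - 1$: a linear coupling of
severity to the shock is exactly linear on that scale, so a noiseless panel
yields $r = 1$ identically, while the back-transformed effect is convex in
$\alpha$ and would attenuate the correlation by construction. The
`scale = "linear"` option reproduces the back-transformed variant.

## The synthetic-data generator

The generator is first-class, tested code, and defines the conditions under
which the pipeline is validated.

**Interest.** Two 52-week years share one seasonal component — a log-linear
trend in week-of-year plus multiplicative holiday bumps (default weeks
51–52, multiplier 1.5, emulating end-of-year holiday peaks) — and the
treatment year adds the quadratic shock
$\alpha + \beta t + \gamma t^2$ to post-cutoff weeks only. Noise is
lognormal: Gaussian on the log scale, i.i.d. per week. The baseline level
defaults to 100 volume units and the cutoff to week 12 (mid-March), so the
default holiday weeks stay outside the default fit window. Two properties
follow by construction and anchor the tests: with no shock and no noise the
two years are identical, and the generative model is *nested* in the
quadratic regression, so injected $(\alpha, \beta, \gamma)$ are recovered
exactly (to numerical tolerance) from noiseless data.

The noise distribution is our modeling choice, not an empirical claim about
search data: lognormal multiplicative noise matches the fitted log-OLS error
model, which makes coverage tests well-specified (the measured 95% CI
coverage is then a check of the estimation machinery, not of a
distributional approximation).

**Mobility.** A daily percent-change curve over February–December: zero
before onset, a raised-cosine rise over `rise_days` (default 14) to the peak
severity, a plateau (default 45 days, long enough that the 7-day smoother
reproduces the peak exactly), a raised-cosine recovery (default 60 days),
and an optional second wave that must begin after the first has fully
recovered and persists to the end of the year. Gaussian daily noise is
added.

**Panels.** `generate_country_panel()` spreads severities evenly over a
range (default 10.1–31.6%, the span from lenient to severe lockdowns) and
couples them to the true shock via
$\alpha = \text{dose\_slope} \cdot \text{severity}/100$, optionally with
country-level noise. The interest-shock cutoff for each country is placed
at the week of the *detected* (noiseless, smoothed) mobility threshold
crossing rather than the raw onset day: in the study design the cutoff is
by definition the detected mobility decrease, and aligning the generator
with it makes end-to-end recovery exact rather than approximately right.
The recorded truth (`severity`, `alpha`, `cutoff_week`) matches the
generator inputs exactly.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: integer rounding and renormalisation of raw
search indices, calibration error between entities, serially correlated or
heteroskedastic noise, week-53 years, data gaps, cross-country correlation
of shocks, and shocks that are not quadratic-in-time. Tests against the
generator validate the estimation machinery under the model's own
assumptions; they cannot validate those assumptions against the world.

## Problem sizes used in the test-suite and acceptance runs

Fits use the study-scale 82-row design throughout. Monte-Carlo checks use
500 replicates for CI coverage (noise SD 0.1 on the log scale), 300 for the
bias check, 1000 replicates at $n = 46$ for the Spearman null calibration,
15 replicates for the reversion-week recovery (the crossing week has about
a one-week sampling jitter, so the median is compared to the independent
design-geometry oracle within $\pm 1$), and an 18-country panel for
dose-response recovery. End-to-end pipeline tests run 3 synthetic countries
over the bundled 28-entity synthetic catalog (12 food entities in 4
categories plus the 16 access-mode entities), a deliberately small but
structurally complete study.

## Known limitations

* Classical standard errors ignore the serial correlation that weekly
  series plausibly have; the intervals are exactly those of the study
  design the package implements, not the most conservative possible.
* The reversion criterion depends on CI width and hence on the noise level:
  noisier series revert "sooner" by construction. Comparisons of reversion
  times across series of very different noise levels should be read with
  that in mind.
* The 2x2 access-mode grouping and the food-category taxonomy are consumed
  from a catalog file, not built; the bundled catalog is synthetic and
  labelled as such.
* `run_study()` degrades per-series (a failed series is recorded in the
  manifest and skipped), which mirrors per-country/per-category reporting
  with missing cells but means a silently sparse result table is possible —
  always check the manifest's failure count.
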