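Package: dietshift
Title: Dietary Search-Interest Shifts Under Mobility Restrictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring population-scale shifts in dietary interest
    from calibrated weekly search-volume panels and daily residential-mobility
    series. Detects mobility changepoints by smoothing and thresholding,
    fits a difference-in-discontinuities regression (a regression
    discontinuity design with a seasonal control year) to log search volume,
    and derives short-term effects, reversion times and long-term effects on
    the multiplicative scale. Also computes z-score surplus-of-interest
    metrics with holiday reference weeks, seasonality-adjusted Spearman
    correlations between mobility and interest, and cross-country
    dose-response summaries of lockdown severity against estimated effects.
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
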