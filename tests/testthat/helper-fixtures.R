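# Shared fixture builders; everything is generated in code at test time.

# a plain hand-built interest series on the full 104-week grid
make_series <- function(volumes_2019, volumes_2020 = volumes_2019,
                        country = "US", label = "test") {
  interest_series(
    country = country, label = label,
    year = rep(c(2019L, 2020L), each = length(volumes_2019)),
    week = c(seq_along(volumes_2019), seq_along(volumes_2020)),
    volume = c(volumes_2019, volumes_2020)
  )
}

# noiseless seasonal series with an injected quadratic shock
shock_params <- function(alpha = 0, beta = 0, gamma = 0, sigma = 0,
                         seed = 1L, cutoff = 12L, ...) {
  seasonal_shock_params(
    shock_log_effect = alpha, shock_decay = c(beta, gamma),
    noise_sigma = sigma, seed = seed, cutoff_week_of_year = cutoff, ...
  )
}

default_spec <- function(cutoff = 12L, form = "quadratic", ...) {
  model_spec(cutoff_week = cutoff, form = form, ...)
}

# closed-form OLS via the normal equations: the independent oracle used to
# check the fitted coefficients
normal_equations_fit <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

synthetic_catalog_path <- function() {
  system.file("extdata", "catalog_synthetic.csv", package = "dietshift")
}
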