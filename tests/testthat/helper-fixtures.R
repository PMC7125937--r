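# Shared fixtures built in code.

# Ten synthetic city curves at the reference-city SMTs, generated from the
# primary published constants (known ground truth).
make_ten_cities <- function(noise_sd = 0, seed = 1L, t_range = 10) {
  smts <- us_city_smt()
  lapply(seq_along(smts), function(i) {
    gen_city_erf(synthetic_city_spec(
      smt_true = smts[[i]], noise_sd = noise_sd, t_range = t_range,
      city_id = names(smts)[i], seed = seed + i))
  })
}

# Small deterministic temperature grid (no noise unless asked).
make_tiny_grid <- function(n_lat = 2L, n_lon = 2L, years = 2010:2011,
                           daily_sd = 0, trend = 0, seed = 1L,
                           smt_band = c(-Inf, Inf), ...) {
  gen_temperature_grid(climate_spec(
    n_lat = n_lat, n_lon = n_lon, years = years, daily_sd = daily_sd,
    trend = trend, seed = seed, smt_band = smt_band, ...))
}

# Independent OLS oracle: normal equations solved directly.
ols_oracle <- function(X, y) {
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
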