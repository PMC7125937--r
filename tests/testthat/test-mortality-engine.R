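test_that("daily baseline rates integrate back to the annual rate", {
  bm <- baseline_mortality(0.0087, days_in_month() / 365)
  expect_equal(daily_baseline_rate(bm), rep(0.0087 / 365, 365),
               tolerance = 1e-12)
  bm2 <- baseline_mortality(0.0087, gen_monthly_weights(0.2))
  expect_equal(sum(daily_baseline_rate(bm2)), 0.0087, tolerance = 1e-12)
  # January share 0.10: any January day's rate is annual * 0.10 / 31
  shares <- c(0.10, rep(0.90 / 11, 11))
  bm3 <- baseline_mortality(0.0087, shares)
  expect_equal(daily_baseline_rate(bm3, doy = 15), 0.0087 * 0.10 / 31,
               tolerance = 1e-15)
  expect_error(daily_baseline_rate(bm3, doy = 366), "input error")
  expect_error(baseline_mortality(0), "annual_rate")
  expect_error(baseline_mortality(0.008, rep(0.1, 12)), "summing to 1")
})

test_that("attributable deaths follow pop x rate x (RR - 1)", {
  expect_equal(attributable_deaths(1e6, 2.5e-5, 1.2), 5)
  expect_equal(attributable_deaths(1e6, 2.5e-5, 1), 0)
  # conventional attributable-fraction variant for sensitivity runs
  expect_equal(attributable_deaths(1e6, 2.5e-5, 1.2, "excess_over_rr"),
               25 * 0.2 / 1.2)
  expect_error(attributable_deaths(-1, 1e-5, 1.1), "input error")
})

test_that("grid-day death totals equal a brute-force triple loop", {
  set.seed(41)
  n_cell <- 12L; n_day <- 30L
  pop <- sample(1e3:1e5, n_cell)
  rate <- runif(n_day, 1e-5, 5e-5)
  rr <- matrix(1 + rexp(n_cell * n_day, rate = 20), n_cell, n_day)
  got <- attributable_deaths(pop, rep(rate, each = n_cell), rr)
  oracle <- 0
  for (c in seq_len(n_cell)) for (d in seq_len(n_day)) {
    oracle <- oracle + pop[c] * rate[d] * (rr[c, d] - 1)
  }
  expect_equal(sum(got), oracle, tolerance = 1e-9 * abs(oracle))
})

test_that("projection is zero when no day exceeds the optimal temperature", {
  tg <- make_tiny_grid(annual_mean = 20, lat_range = 0,
                       seasonal_amplitude = 0, years = 2010:2011)
  pop <- matrix(1e5, 2, 2)
  bm <- baseline_mortality(0.008)
  exp0 <- list(ot = matrix(25, 2, 2), smt = matrix(24, 2, 2))
  res <- project_scenario(tg, pop, bm, exp0, erf_preset("eq2_variantA"))
  expect_true(all(res$deaths_by_cell_year == 0))
  expect_equal(res$decadal_mean, 0)
})

test_that("a decade of identical years has decadal mean equal to any year", {
  tg <- make_tiny_grid(annual_mean = 24, lat_range = 0, years = 2010:2013)
  pop <- matrix(c(1e5, 2e5, 0, 5e4), 2, 2)
  bm <- baseline_mortality(0.008)
  ef <- exposure_fields(tg)
  res <- project_scenario(tg, pop, bm, ef, erf_preset("eq2_variantA"))
  expect_equal(unname(res$annual_totals),
               rep(res$annual_totals[[1]], 4), tolerance = 1e-12)
  expect_equal(res$decadal_mean, res$annual_totals[[1]], tolerance = 1e-12)
})

test_that("small-fixture projection equals a hand accumulation", {
  # 3 populated cells, 2 years, noisy temperatures: accumulate by loop
  tg <- gen_temperature_grid(climate_spec(
    n_lat = 3L, n_lon = 1L, years = 2010:2011, annual_mean = 22,
    lat_range = 4, seasonal_amplitude = 8, daily_sd = 2, seed = 8L,
    smt_band = c(-Inf, Inf)))
  pop <- matrix(c(1e4, 2e4, 3e4), 3, 1)
  bm <- baseline_mortality(0.009, gen_monthly_weights(0.2))
  ef <- exposure_fields(tg)
  p <- erf_preset("eq2_variantA")
  res <- project_scenario(tg, pop, bm, ef, p, pop_scale = 1.1)

  rate <- daily_baseline_rate(bm, rep(1:365, 2))
  oracle <- matrix(0, 3, 2)
  for (c in 1:3) for (d in seq_len(730)) {
    rr <- as.numeric(relative_risk(tg[c, 1, d], ef$ot[c, 1], ef$smt[c, 1], p))
    oracle[c, (d - 1) %/% 365 + 1] <- oracle[c, (d - 1) %/% 365 + 1] +
      1.1 * pop[c, 1] * rate[d] * (rr - 1)
  }
  expect_equal(res$deaths_by_cell_year, oracle, tolerance = 1e-9)
})

test_that("projection checks grid alignment", {
  tg <- make_tiny_grid(years = 2010)
  bm <- baseline_mortality(0.008)
  ef <- exposure_fields(tg)
  expect_error(project_scenario(tg, matrix(1, 3, 2), bm, ef,
                                erf_preset("eq2_variantA")),
               "alignment error")
  expect_error(project_scenario(tg, matrix(1, 2, 2), bm,
                                list(ot = matrix(25, 1, 1),
                                     smt = matrix(24, 1, 1)),
                                erf_preset("eq2_variantA")),
               "alignment error")
})

test_that("doubling population exactly doubles all death aggregates", {
  tg <- make_tiny_grid(annual_mean = 24, daily_sd = 2, years = 2010:2011)
  pop <- matrix(c(1e5, 2e5, 3e5, 4e5), 2, 2)
  bm <- baseline_mortality(0.008)
  ef <- exposure_fields(tg)
  p <- erf_preset("eq2_variantA")
  r1 <- project_scenario(tg, pop, bm, ef, p)
  r2 <- project_scenario(tg, 2 * pop, bm, ef, p)
  expect_equal(r2$deaths_by_cell_year, 2 * r1$deaths_by_cell_year,
               tolerance = 1e-12)
  expect_equal(r2$decadal_mean, 2 * r1$decadal_mean, tolerance = 1e-12)
})

test_that("national total equals the sum over states and over cells", {
  tg <- make_tiny_grid(n_lat = 4L, n_lon = 3L, annual_mean = 24,
                       daily_sd = 2, years = 2010)
  pop <- gen_population_grid(4L, 3L, 1e6, seed = 2L)
  bm <- baseline_mortality(0.008)
  res <- project_scenario(tg, pop, bm, exposure_fields(tg),
                          erf_preset("eq2_variantA"))
  masks <- gen_region_masks(4L, 3L, n_states = 2L)
  agg <- aggregate_regions(res, masks)
  expect_equal(sum(agg$state$deaths_per_year), res$decadal_mean,
               tolerance = 1e-9)
  expect_equal(sum(res$deaths_by_cell_year) / length(res$years),
               res$decadal_mean, tolerance = 1e-12)
  expect_true(all(res$deaths_by_cell_year >= 0))
})

test_that("regional aggregation matches hand computation on two states", {
  res <- structure(list(
    deaths_by_cell_year = matrix(c(10, 20, 30, 40), 4, 1),
    pop = c(1e6, 1e6, 2e6, 2e6),
    years = 2010), class = "mortality_result")
  masks <- list(state = matrix(c("N", "N", "S", "S"), 4, 1),
                city_boxes = list(A = c(1L, 3L), empty = integer(0)))
  agg <- aggregate_regions(res, masks)
  expect_equal(agg$state$deaths_per_year, c(30, 70))
  expect_equal(agg$state$per_capita_million, c(30 / 2, 70 / 4))
  expect_equal(agg$city_boxes$deaths_per_year, c(10 + 30, 0))
  # single state covering everything reproduces the national rate
  masks1 <- list(state = matrix("US", 4, 1), city_boxes = list())
  agg1 <- aggregate_regions(res, masks1)
  expect_equal(agg1$state$per_capita_million, 100 / 6e6 * 1e6)
  bad <- list(state = matrix(c("N", NA, "S", "S"), 4, 1), city_boxes = list())
  expect_error(aggregate_regions(res, bad), "mask error")
})

test_that("observed-curve lookup interpolates, clamps, and counts overflow", {
  tt <- seq(0, 5, by = 0.1)
  cv <- erf_curve("c", smt = 28, ot = 25, temp = 25 + tt,
                  rr = 1 + 0.01 * tt)
  rr <- observed_rr(cv, c(20, 25, 27.05, 40))
  expect_equal(as.numeric(rr), c(1, 1, 1 + 0.01 * 2.05, 1.05),
               tolerance = 1e-12)
  expect_equal(attr(rr, "n_above_range"), 1L)
})

test_that("evaluation report is a zero-error row when the generalized
           parameters reproduce the city's own quadratic", {
  # SMT above the linear x-intercept so neither side clamps
  sp <- synthetic_city_spec(smt_true = 28, noise_sd = 0, t_range = 8)
  cv <- gen_city_erf(sp)
  set.seed(51)
  # daily temps on the 0.1 degC sample grid so lookup interpolation is exact
  t_day <- attr(cv, "ot") + round(runif(365, -20, 75)) / 10
  rep_df <- evaluation_report(
    curves = list(city = cv), params = erf_preset("eq2_variantA"),
    city_temps = list(city = t_day), city_pop = c(city = 1e6),
    bm = baseline_mortality(0.008))
  expect_equal(rep_df$abs_error[1], 0, tolerance = 1e-9)
  expect_equal(rep_df$generalized[1], rep_df$observed[1], tolerance = 1e-9)
})

test_that("bias table recomputes totals-row errors from the column sums", {
  bt <- bias_table(c("x", "y"), c(100, 50), c(80, 100))
  expect_equal(bt$abs_error, c(20, -50, -30))
  expect_equal(bt$rel_error_pct, c(25, -50, round(-30 / 180 * 100)))
  expect_equal(bt$city[3], "Total")
})
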