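test_that("noise-free quadratic curves are recovered exactly by both variants", {
  tt <- seq(0, 10, by = 0.1)
  cv <- erf_curve("c1", smt = 24, ot = 27, temp = 27 + tt,
                  rr = 1 + 0.002 * tt^2 + 0.01 * tt)
  for (v in c("A", "B")) {
    cf <- fit_city_polynomial(cv, variant = v)
    expect_equal(cf$a, 0.002, tolerance = 1e-10)
    expect_equal(cf$b, 0.01, tolerance = 1e-10)
    expect_equal(cf$offset, 0, tolerance = 1e-10)
  }
  flat <- erf_curve("c2", smt = 24, ot = 27, temp = 27 + tt,
                    rr = rep(1, length(tt)))
  cf <- fit_city_polynomial(flat)
  expect_equal(cf$a, 0, tolerance = 1e-12)
  expect_equal(cf$b, 0, tolerance = 1e-12)
})

test_that("fits ignore the cold side and reject degenerate curves", {
  tt <- seq(-5, 10, by = 0.1)
  rr <- ifelse(tt >= 0, 1 + 0.002 * tt^2 + 0.01 * tt, 5)  # garbage cold side
  cv <- erf_curve("c", smt = 24, ot = 27, temp = 27 + tt, rr = rr)
  cf <- fit_city_polynomial(cv)
  expect_equal(cf$a, 0.002, tolerance = 1e-10)
  short <- erf_curve("s", smt = 24, ot = 27, temp = 27 + c(-0.2, -0.1, 0, 0.1),
                     rr = rep(1, 4))
  expect_error(fit_city_polynomial(short), "degenerate")
})

test_that("noisy fits equal the hand-coded normal-equations oracle", {
  set.seed(101)
  tt <- seq(0, 8, by = 0.1)
  rr <- pmax(0, 1 + 0.004 * tt^2 - 0.01 * tt + rnorm(length(tt), sd = 0.02))
  cv <- erf_curve("noisy", smt = 23, ot = 25, temp = 25 + tt, rr = rr)

  cfA <- fit_city_polynomial(cv, variant = "A")
  betaA <- ols_oracle(cbind(1, tt, tt^2), rr)
  expect_equal(cfA$a, betaA[3], tolerance = 1e-8)
  expect_equal(cfA$b, betaA[2], tolerance = 1e-8)
  expect_equal(cfA$offset, betaA[1] - 1, tolerance = 1e-8)

  cfB <- fit_city_polynomial(cv, variant = "B")
  betaB <- ols_oracle(cbind(tt, tt^2), rr - 1)
  expect_equal(cfB$a, betaB[2], tolerance = 1e-8)
  expect_equal(cfB$b, betaB[1], tolerance = 1e-8)
})

test_that("coefficient regression recovers an exact line", {
  smts <- c(20, 22, 24, 26, 28)
  df <- data.frame(smt = smts, a = -0.002 * (smts - 30), b = 0.004 * (smts - 26))
  p <- regress_coefficients(df)
  expect_equal(p$slope_a, -0.002, tolerance = 1e-12)
  expect_equal(p$xint_a, 30, tolerance = 1e-10)
  expect_equal(p$slope_b, 0.004, tolerance = 1e-12)
  expect_equal(p$xint_b, 26, tolerance = 1e-10)
  expect_error(regress_coefficients(df[1:2, ]), ">= 3 points")
  flat <- data.frame(smt = smts, a = rep(0.01, 5), b = 0.004 * (smts - 26))
  expect_error(regress_coefficients(flat), "non-identifiable")
})

test_that("ten noise-free reference-SMT cities recover the published constants", {
  coefs <- lapply(make_ten_cities(noise_sd = 0), fit_city_polynomial,
                  variant = "A")
  p <- regress_coefficients(coefs)
  expect_equal(p$slope_a, -0.0014, tolerance = 1e-6)
  expect_equal(p$xint_a, 30.9, tolerance = 1e-6)
  expect_equal(p$slope_b, 0.005, tolerance = 1e-6)
  expect_equal(p$xint_b, 26.7, tolerance = 1e-6)
})

test_that("noisy coefficient regression slopes match the OLS oracle", {
  coefs <- lapply(make_ten_cities(noise_sd = 0.01, seed = 7L),
                  fit_city_polynomial, variant = "A")
  p <- regress_coefficients(coefs)
  smt <- vapply(coefs, `[[`, numeric(1), "smt")
  a <- vapply(coefs, `[[`, numeric(1), "a")
  b <- vapply(coefs, `[[`, numeric(1), "b")
  ba <- ols_oracle(cbind(1, smt), a)
  bb <- ols_oracle(cbind(1, smt), b)
  expect_equal(p$slope_a, ba[2], tolerance = 1e-8)
  expect_equal(p$xint_a, -ba[1] / ba[2], tolerance = 1e-8)
  expect_equal(p$slope_b, bb[2], tolerance = 1e-8)
  expect_equal(p$r_a, cor(smt, a), tolerance = 1e-12)
})

test_that("generalized relative risk matches hand evaluations and clamps", {
  p <- erf_preset("eq2_variantA")
  # below or at the optimal temperature the risk is exactly 1
  expect_equal(as.numeric(relative_risk(c(10, 24.9, 25), 25, 28, p)),
               c(1, 1, 1))
  # SMT 25.7, T = 5: 1 + (-0.0014)(25.7-30.9)*25 + 0.005*(25.7-26.7)*5
  expect_equal(as.numeric(relative_risk(30, 25, 25.7, p)), 1.157,
               tolerance = 1e-12)
  # SMT 20, T = 1 dips below 1 unclamped and is lifted to 1
  expect_equal(as.numeric(relative_risk(26, 25, 20, p, clamp = FALSE)),
               0.98176, tolerance = 1e-12)
  rr <- relative_risk(26, 25, 20, p)
  expect_equal(as.numeric(rr), 1)
  expect_equal(attr(rr, "n_clamped"), 1L)
  expect_error(relative_risk(NA_real_, 25, 20, p), "input error")
})

test_that("risk above the quadratic sign-change SMT is counted, not an error", {
  p <- erf_preset("eq2_variantA")
  rr <- relative_risk(c(30, 31), 25, 32, p)   # SMT 32 > 30.9
  expect_equal(attr(rr, "n_smt_above_xint"), 2L)
})

test_that("clamped risk is >= 1 everywhere and 1 below OT (property)", {
  p <- erf_preset("eq2_variantA")
  set.seed(11)
  for (i in 1:50) {
    ot <- runif(1, 10, 30)
    smt <- runif(1, 18, 32)
    t_day <- runif(20, -10, 45)
    rr <- as.numeric(relative_risk(t_day, ot, smt, p))
    expect_true(all(rr >= 1))
    expect_true(all(rr[t_day <= ot] == 1))
  }
})

test_that("for SMT below the sign-change point the curve is convex and
           nondecreasing beyond the vertex", {
  p <- erf_preset("eq2_variantA")
  for (smt in c(20, 24, 28, 30.5)) {
    a <- p$slope_a * (smt - p$xint_a)
    b <- p$slope_b * (smt - p$xint_b)
    expect_gt(a, 0)                           # convex unclamped parabola
    t0 <- max(0, -b / (2 * a))
    tt <- seq(t0, t0 + 15, by = 0.1)
    rr <- as.numeric(relative_risk(25 + tt, 25, smt, p))
    expect_true(all(diff(rr) >= -1e-12))
  }
})

test_that("leave-one-out slopes collapse to zero spread on exact lines", {
  smts <- c(20, 21.5, 23, 24.5, 26, 27.5)
  df <- data.frame(smt = smts, a = -0.0014 * (smts - 30.9),
                   b = 0.005 * (smts - 26.7))
  s <- loo_sensitivity(df)
  expect_equal(s$sd_rel_a, 0, tolerance = 1e-9)
  expect_equal(s$max_rel_a, 0, tolerance = 1e-9)
  expect_equal(s$sd_rel_b, 0, tolerance = 1e-9)
})

test_that("each leave-one-out refit equals a from-scratch OLS on the
           reduced set", {
  coefs <- lapply(make_ten_cities(noise_sd = 0.02, seed = 3L),
                  fit_city_polynomial)
  df <- data.frame(smt = vapply(coefs, `[[`, numeric(1), "smt"),
                   a = vapply(coefs, `[[`, numeric(1), "a"),
                   b = vapply(coefs, `[[`, numeric(1), "b"))
  s <- loo_sensitivity(df)
  for (i in seq_len(nrow(df))) {
    ba <- ols_oracle(cbind(1, df$smt[-i]), df$a[-i])
    bb <- ols_oracle(cbind(1, df$smt[-i]), df$b[-i])
    expect_equal(s$loo$slope_a[i], ba[2], tolerance = 1e-12)
    expect_equal(s$loo$slope_b[i], bb[2], tolerance = 1e-12)
  }
  expect_true(is.finite(s$sd_rel_a) && is.finite(s$max_rel_a))
  expect_error(loo_sensitivity(df[1:3, ]), ">= 4 points")
})

test_that("generalized curves correlate strongly with each city's truth", {
  curves <- make_ten_cities(noise_sd = 0.01, seed = 21L)
  p <- regress_coefficients(lapply(curves, fit_city_polynomial))
  r2 <- vapply(curves, function(cv) {
    truth <- attr(cv, "truth")
    tt <- cv$temp - attr(cv, "ot")
    rr_true <- 1 + truth$a * tt^2 + truth$b * tt
    rr_gen <- as.numeric(relative_risk(cv$temp, attr(cv, "ot"),
                                       attr(cv, "smt"), p, clamp = FALSE))
    cor(rr_true, rr_gen)^2
  }, numeric(1))
  expect_true(all(r2 >= 0.95))
})

test_that("curve CSV round-trips preserve samples and metadata", {
  curves <- make_ten_cities(noise_sd = 0.01, seed = 2L)[1:3]
  path <- withr::local_tempfile(fileext = ".csv")
  write_erf_csv(curves, path)
  back <- read_erf_csv(path)
  expect_length(back, 3L)
  expect_equal(back[[1]]$rr, curves[[1]]$rr, tolerance = 1e-12)
  expect_equal(attr(back[[2]], "smt"), attr(curves[[2]], "smt"))
  expect_equal(attr(back[[3]], "ot"), attr(curves[[3]], "ot"))
})
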