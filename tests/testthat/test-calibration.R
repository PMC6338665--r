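test_that("noise-free points recover (C, k) exactly", {
  p <- sat_points()
  fit <- fit_calibration(p$o2, p$moto, n_mc = 0)
  expect_equal(fit$C, 0.243, tolerance = 1e-7)
  expect_equal(fit$k, 0.0088, tolerance = 1e-7)
})

test_that("forward curve and inversion are mutual inverses on (0, C)", {
  cv <- calibration_curve(C = 0.243, k = 0.0088)
  o2 <- c(1, 10, 60.2, 150, 400)
  m <- calibration_predict(cv, o2)
  back <- sapply(m, function(mi) moto_to_fmr(mi, cv)$point)
  expect_equal(back, o2, tolerance = 1e-10)
  # and the documented point value
  expect_equal(moto_to_fmr(0.10, cv)$point, 60.2, tolerance = 1e-3)
})

test_that("inversion limit M -> 0 gives O2 -> 0 and M >= C censors", {
  cv <- calibration_curve(C = 0.243, k = 0.0088)
  expect_equal(moto_to_fmr(1e-12, cv)$point, 0, tolerance = 1e-3)
  est <- suppressWarnings(moto_to_fmr(0.30, cv))
  expect_true(est$unreliable)
  expect_true(is.na(est$point))
})

test_that("fitted curve is monotone increasing, concave and bounded by C", {
  p <- sat_points()
  fit <- fit_calibration(p$o2, p$moto, n_mc = 0)
  o2 <- seq(0, 1000, by = 10)
  m <- calibration_predict(fit, o2)
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(diff(m)) < 1e-12))
  expect_true(all(m < fit$C))
})

test_that("Monte Carlo ensemble recovers generator truth on rearing data", {
  set.seed(31)
  d <- rearing_design(n_per_group = 16, seed = 31)
  sim <- simulate_rearing(d)
  em <- d$ends
  moto <- compute_moto(sim$samples$d13C_oto, em)
  moto_sd <- moto_sd_delta_method(sim$samples$d13C_oto, em)
  fit <- fit_calibration(sim$truth$rmr, moto,
                         o2_sd = 0.05 * sim$truth$rmr, moto_sd = moto_sd,
                         n_mc = 400, seed = 32)
  expect_lt(abs(fit$C - 0.243), 2 * fit$ensemble_sd["C"])
  expect_lt(abs(fit$k - 0.0088), 2 * fit$ensemble_sd["k"])
})

test_that("censoring fraction above one half flags the estimate unreliable", {
  cv <- calibration_curve(C = 0.243, k = 0.0088)
  est <- suppressWarnings(moto_to_fmr(0.25, cv, moto_sd = 0.001,
                                      n_draws = 2000, seed = 4))
  expect_true(est$unreliable)
  expect_gt(est$censored_frac, 0.5)
})

test_that("precision report: zero input SDs give zero output SD", {
  cv <- calibration_curve(0.243, 0.0088)
  em <- endmembers(-0.18, -20.13, d13C_DIC_sd = 0, d13C_diet_sd = 0)
  rep0 <- fmr_precision_report(-2.9, em, cv, d13C_oto_sd = 0,
                               n_draws = 2000, seed = 5)
  expect_equal(rep0$fmr_sd, 0, tolerance = 1e-9)
})

test_that("precision report SD grows with otolith SD and fractions sum to 1", {
  cv <- calibration_curve(0.243, 0.0088)
  em <- endmembers(-0.18, -20.13)
  lo <- fmr_precision_report(-2.9, em, cv, d13C_oto_sd = 0.1,
                             n_draws = 4000, seed = 6)
  hi <- fmr_precision_report(-2.9, em, cv, d13C_oto_sd = 0.4,
                             n_draws = 4000, seed = 6)
  expect_gt(hi$fmr_sd, lo$fmr_sd)
  fr <- lo$frac_oto + lo$frac_endmembers + lo$frac_curve
  expect_equal(fr, 1, tolerance = 1e-9)
})

test_that("curve round-trips through the plain-text serialisation", {
  p <- sat_points()
  fit <- fit_calibration(p$o2, p$moto + rnorm(length(p$o2), 0, 0.005),
                         o2_sd = 2, moto_sd = 0.005, n_mc = 50, seed = 7)
  path <- tempfile(fileext = ".txt")
  write_calibration(fit, path)
  back <- read_calibration(path)
  expect_equal(back$C, fit$C, tolerance = 1e-12)
  expect_equal(back$k, fit$k, tolerance = 1e-12)
  expect_equal(nrow(back$ensemble), nrow(fit$ensemble))
  expect_error(read_calibration(tempfile()), "not found")
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_calibration(c(50, 50, 50), c(0.1, 0.1, 0.1)), "distinct")
})
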