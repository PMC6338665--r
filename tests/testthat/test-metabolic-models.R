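test_that("Arrhenius factor and scaling identities hold", {
  m <- mte_model(B0 = 1, alpha = 0)
  # independent scalar evaluation of the Boltzmann factor at 283.15 K
  expect_equal(mte_predict(m, 1, 283.15), 2.72e-12, tolerance = 1e-3)
  m25 <- mte_model(B0 = 5e13, alpha = -0.25)
  expect_equal(mte_predict(m25, 200, 280) / mte_predict(m25, 100, 280),
               2^-0.25, tolerance = 1e-12)
  m0 <- mte_model(B0 = 5e13, alpha = 0)
  expect_equal(mte_predict(m0, 500, 280), mte_predict(m0, 5, 280))
})

test_that("mte_predict is increasing in T and decreasing in mass for alpha<0", {
  m <- mte_model(B0 = 8.04e13, alpha = -0.25)
  temps <- seq(275, 290, by = 1)
  expect_true(all(diff(mte_predict(m, 300, temps)) > 0))
  masses <- seq(100, 700, by = 50)
  expect_true(all(diff(mte_predict(m, masses, 283.15)) < 0))
})

test_that("fit_B0 recovers the truth exactly on noise-free data", {
  set.seed(5)
  mass <- runif(17, 94, 783)
  temp_K <- sample(c(4, 7, 10, 14), 17, replace = TRUE) + 273.15
  truth <- mte_model(B0 = 8.04e13, alpha = -0.25)
  smr <- mte_predict(truth, mass, temp_K)
  fit <- suppressWarnings(fit_B0(mass, temp_K, smr))  # exact-fit warning
  expect_equal(fit$B0, 8.04e13, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # regression idempotence: predictions reproduce the fitted values
  expect_equal(mte_predict(fit$model, mass, temp_K), smr, tolerance = 1e-10)
})

test_that("fit_B0 is unbiased within Monte Carlo error under noise", {
  set.seed(6)
  est <- replicate(100, {
    mass <- runif(17, 94, 783)
    temp_K <- sample(c(4, 7, 10, 14), 17, replace = TRUE) + 273.15
    smr <- mte_predict(mte_model(8.04e13), mass, temp_K) * rnorm(17, 1, 0.1)
    fit_B0(mass, temp_K, smr)$B0
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 8.04e13), 3 * se)
})

test_that("fit_B0 R^2 matches the origin-constrained 1 - RSS/TSS oracle", {
  set.seed(7)
  mass <- runif(20, 94, 783)
  temp_K <- runif(20, 277, 288)
  smr <- mte_predict(mte_model(8.04e13), mass, temp_K) * rnorm(20, 1, 0.15)
  fit <- fit_B0(mass, temp_K, smr)
  x <- mass^-0.25 * exp(-0.65 / (8.62e-5 * temp_K))
  rss <- sum((smr - fit$B0 * x)^2)
  expect_equal(fit$r_squared, 1 - rss / sum(smr^2), tolerance = 1e-10)
})

test_that("smr_to_rmr moments match the multiplier distribution", {
  det <- smr_to_rmr(100, multiplier_sd = 0, n_draws = 1000)
  expect_equal(det$mean, 155)
  expect_equal(det$sd, 0)
  st <- smr_to_rmr(100, n_draws = 50000, seed = 9)
  expect_equal(mean(st$draws), 155, tolerance = 0.01)
  expect_equal(sd(st$draws), 8.32, tolerance = 0.05)
})

test_that("swim-tunnel extrapolation recovers the intercept exactly", {
  speed <- seq(0.2, 1.2, by = 0.2)
  mo2 <- 45 * exp(0.8 * speed)
  fit <- smr_from_swim(speed, mo2)
  expect_equal(fit$smr, 45, tolerance = 1e-10)
  expect_equal(fit$b, 0.8, tolerance = 1e-10)
})

test_that("flat speed response returns the mean MO2 and b near 0", {
  speed <- seq(0.2, 1.2, by = 0.2)
  fit <- smr_from_swim(speed, rep(52, 6))
  expect_equal(fit$smr, 52, tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
})

test_that("log-OLS and direct NLS agree on noise-free input", {
  speed <- seq(0.2, 1.2, by = 0.2)
  mo2 <- 38 * exp(0.65 * speed)
  a <- smr_from_swim(speed, mo2, method = "log-ols")
  b <- smr_from_swim(speed, mo2, method = "nls")
  expect_equal(a$smr, b$smr, tolerance = 1e-6)
})

test_that("SMR estimate sits below the minimum observed MO2 when b > 0", {
  set.seed(12)
  speed <- rep(seq(0.2, 1.2, by = 0.2), 2)
  mo2 <- 45 * exp(0.7 * speed) * exp(rnorm(length(speed), 0, 0.05))
  fit <- smr_from_swim(speed, mo2)
  expect_gt(fit$b, 0)
  expect_lt(fit$smr, min(mo2))
})

test_that("exclusion flags are honoured and guards fire", {
  speed <- seq(0.2, 1.2, by = 0.2)
  mo2 <- 45 * exp(0.8 * speed)
  mo2[3] <- 500  # wild loop, flagged
  fit <- smr_from_swim(speed, mo2, excluded = c(F, F, T, F, F, F))
  expect_equal(fit$smr, 45, tolerance = 1e-10)
  expect_error(smr_from_swim(speed[1:2], mo2[1:2]), ">= 3")
  expect_error(smr_from_swim(speed, -mo2), "positive")
})
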