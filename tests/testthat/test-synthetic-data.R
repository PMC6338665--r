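test_that("noise-free rearing data round-trip through the mixing model", {
  d <- rearing_design(n_per_group = 5, d13C_oto_sd = 0, d18O_oto_sd = 0,
                      rmr_multiplier_sd = 0, seed = 71)
  sim <- simulate_rearing(d)
  m_back <- compute_moto(sim$samples$d13C_oto, d$ends)
  expect_equal(m_back, sim$truth$m_true, tolerance = 1e-12)
  # and all the way to oxygen consumption through the true curve
  cv <- calibration_curve(d$true_C, d$true_k)
  o2_back <- sapply(m_back, function(m) moto_to_fmr(m, cv)$point)
  expect_equal(o2_back, sim$truth$rmr, tolerance = 1e-8)
})

test_that("simulated M_oto increases with rearing temperature", {
  d <- rearing_design(temperatures = c(4, 14), n_per_group = 40,
                      mass_range = c(300, 300), seed = 72)
  sim <- simulate_rearing(d)
  m4 <- mean(sim$truth$m_true[sim$samples$temperature_nominal_C == 4])
  m14 <- mean(sim$truth$m_true[sim$samples$temperature_nominal_C == 14])
  expect_gt(m14, m4)
})

test_that("rearing generator is deterministic under a fixed seed", {
  a <- simulate_rearing(rearing_design(n_per_group = 4, seed = 73))
  b <- simulate_rearing(rearing_design(n_per_group = 4, seed = 73))
  expect_identical(a, b)
})

test_that("masses are drawn within range and truth tables stay separate", {
  d <- rearing_design(n_per_group = 30, seed = 74)
  sim <- simulate_rearing(d)
  expect_true(all(sim$samples$mass_g >= 94 & sim$samples$mass_g <= 783))
  expect_false(any(c("smr", "rmr", "m_true") %in% names(sim$samples)))
  expect_false(any(c("d13C_oto", "d18O_oto") %in% names(sim$truth)))
})

test_that("downstream calibration fit recovers rearing truth within 2 SE", {
  d <- rearing_design(n_per_group = 16, seed = 75)
  sim <- simulate_rearing(d)
  moto <- compute_moto(sim$samples$d13C_oto, d$ends)
  fit <- fit_calibration(sim$truth$rmr, moto,
                         moto_sd = moto_sd_delta_method(
                           sim$samples$d13C_oto, d$ends),
                         n_mc = 300, seed = 76)
  expect_lt(abs(fit$C - d$true_C), 2 * fit$ensemble_sd["C"])
  expect_lt(abs(fit$k - d$true_k), 2 * fit$ensemble_sd["k"])
})

test_that("inconsistent rearing truth values are rejected", {
  expect_error(rearing_design(true_C = 1.2), "true_C")
  expect_error(rearing_design(n_per_group = 1), "n_per_group")
})

test_that("wild population: constant conditions give flat FMR trajectories", {
  d <- wild_design(n_fish = 4, mass_at_age = function(a) rep(800, length(a)),
                   temperature_at_age = function(a) rep(5, length(a)),
                   mass_cv = 0, seed = 77)
  sim <- simulate_wild_population(d)
  for (f in unique(sim$truth$fish_id)) {
    fmr <- sim$truth$fmr[sim$truth$fish_id == f]
    expect_lt(diff(range(fmr)), 1e-9)
  }
})

test_that("wild population: mass growth with alpha<0 lowers mass-specific FMR", {
  d <- wild_design(n_fish = 6, seed = 78)
  sim <- simulate_wild_population(d)
  for (f in unique(sim$truth$fish_id)) {
    fmr <- sim$truth$fmr[sim$truth$fish_id == f]
    expect_true(all(diff(fmr) < 0))
  }
})

test_that("wild generator is deterministic and masses non-decreasing in age", {
  a <- simulate_wild_population(wild_design(n_fish = 3, seed = 79))
  b <- simulate_wild_population(wild_design(n_fish = 3, seed = 79))
  expect_identical(a, b)
  for (f in unique(a$samples$fish_id))
    expect_false(is.unsorted(a$samples$mass_g[a$samples$fish_id == f]))
})

test_that("species compilation: zero-noise recovery and finite-width profile", {
  d0 <- species_design(residual_sd = 0, true_alpha = -0.105, seed = 80)
  sim0 <- simulate_species_compilation(d0)
  cv <- calibration_curve(d0$true_C, d0$true_k)
  f0 <- fit_alpha(sim0$samples$mass_g, sim0$samples$temperature_C,
                  sim0$samples$m_oto, cv, refine = FALSE)
  expect_equal(f0$alpha_hat, -0.105, tolerance = 1e-12)

  dn <- species_design(residual_sd = 0.03, seed = 81)
  simn <- simulate_species_compilation(dn)
  # residual noise can push a few M_oto above C; those rows are censored
  fn <- suppressWarnings(
    fit_alpha(simn$samples$mass_g, simn$samples$temperature_C,
              simn$samples$m_oto, cv, refine = FALSE))
  w <- diff(fn$support_interval)
  expect_gt(w, 0)      # noise widens the minimum to finite width
  expect_lt(w, 0.5)    # but the profile still localises alpha
})

test_that("species design guards fire", {
  expect_error(species_design(n_species = 2), "n_species")
  expect_error(species_design(residual_sd = -0.1), "residual_sd")
})
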