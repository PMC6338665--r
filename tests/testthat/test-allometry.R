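test_that("noise-free compilation recovers the exponent exactly on the grid", {
  d <- species_design(residual_sd = 0, true_alpha = -0.105, seed = 51)
  sim <- simulate_species_compilation(d)
  fit <- fit_alpha(sim$samples$mass_g, sim$samples$temperature_C,
                   sim$samples$m_oto, calibration_curve(d$true_C, d$true_k),
                   refine = FALSE)
  expect_equal(fit$alpha_hat, -0.105, tolerance = 1e-12)
  expect_equal(fit$whole_organism_alpha, fit$alpha_hat + 1)
  expect_lt(fit$rss_min, 1e-10)
})

test_that("golden-section refinement locates an off-grid exponent", {
  d <- species_design(residual_sd = 0, true_alpha = -0.1073, seed = 52)
  sim <- simulate_species_compilation(d)
  fit <- fit_alpha(sim$samples$mass_g, sim$samples$temperature_C,
                   sim$samples$m_oto, calibration_curve(d$true_C, d$true_k))
  expect_equal(fit$alpha_hat, -0.1073, tolerance = 1e-4)
})

test_that("single-mass input is flagged degenerate with a flat profile", {
  cv <- calibration_curve(0.243, 0.0088)
  m <- rep(100, 10)
  temp <- rep(10, 10)
  moto <- rep(0.12, 10)
  fit <- suppressWarnings(fit_alpha(m, temp, moto, cv, refine = FALSE))
  expect_true(fit$degenerate)
  # B0 absorbs any alpha when mass is constant: every candidate fits exactly
  expect_true(all(fit$aic_profile$rss < 1e-12))
  expect_equal(fit$support_interval, range(fit$aic_profile$alpha))
})

test_that("profile is invariant to row order", {
  d <- species_design(n_species = 30, seed = 53)
  sim <- simulate_species_compilation(d)
  cv <- calibration_curve(d$true_C, d$true_k)
  s <- sim$samples
  f1 <- suppressWarnings(
    fit_alpha(s$mass_g, s$temperature_C, s$m_oto, cv, refine = FALSE,
              alpha_grid = seq(-0.4, 0.1, 0.01)))
  ix <- rev(seq_len(nrow(s)))
  f2 <- suppressWarnings(
    fit_alpha(s$mass_g[ix], s$temperature_C[ix], s$m_oto[ix], cv,
              refine = FALSE, alpha_grid = seq(-0.4, 0.1, 0.01)))
  expect_equal(f1$aic_profile$aic, f2$aic_profile$aic, tolerance = 1e-8)
  expect_equal(f1$alpha_hat, f2$alpha_hat)
})

test_that("rows with M_oto at or above C are excluded with a warning", {
  d <- species_design(n_species = 20, residual_sd = 0, seed = 54)
  sim <- simulate_species_compilation(d)
  s <- sim$samples
  s$m_oto[1] <- 0.25  # above C = 0.243
  cv <- calibration_curve(d$true_C, d$true_k)
  expect_warning(
    fit <- fit_alpha(s$mass_g, s$temperature_C, s$m_oto, cv,
                     refine = FALSE, alpha_grid = seq(-0.2, 0, 0.005)),
    "excluded")
  expect_equal(fit$n_censored, 1)
  expect_equal(fit$alpha_hat, -0.105, tolerance = 1e-12)
})

test_that("ontogenetic series recover species ordering of exponents", {
  set.seed(55)
  cv <- calibration_curve(0.243, 0.0088)
  make_species <- function(name, alpha) {
    mass <- exp(seq(log(5), log(3000), length.out = 15))
    temp <- seq(12, 4, length.out = 15)  # warm juvenile -> cold adult
    smr <- 8.04e13 * mass^alpha * exp(-0.65 / (8.62e-5 * (temp + 273.15)))
    data.frame(species = name, mass_g = mass, temperature_C = temp,
               moto = 0.243 * (1 - exp(-0.0088 * smr)) +
                 rnorm(15, 0, 0.003))
  }
  dat <- rbind(make_species("shallowbody", -0.135),
               make_species("elongate", -0.626))
  fit <- fit_alpha_ontogeny(dat, cv)
  s <- fit$summary
  expect_lt(s$alpha_hat[s$species == "elongate"],
            s$alpha_hat[s$species == "shallowbody"])
  expect_equal(s$alpha_hat[s$species == "shallowbody"], -0.135,
               tolerance = 0.05)
  expect_equal(s$alpha_hat[s$species == "elongate"], -0.626,
               tolerance = 0.1)
})

test_that("temperature-constant series identify alpha from the mass trend", {
  cv <- calibration_curve(0.243, 0.0088)
  mass <- exp(seq(log(10), log(5000), length.out = 12))
  temp <- rep(6, 12)
  smr <- 8.04e13 * mass^-0.2 * exp(-0.65 / (8.62e-5 * (6 + 273.15)))
  moto <- 0.243 * (1 - exp(-0.0088 * smr))
  fit <- fit_alpha(mass, temp, moto, cv, refine = FALSE)
  expect_equal(fit$alpha_hat, -0.2, tolerance = 1e-12)
})

test_that("ontogenetic temperature shift does not bias the exponent", {
  # same species simulated with and without a thermal migration
  cv <- calibration_curve(0.243, 0.0088)
  mass <- exp(seq(log(5), log(4000), length.out = 20))
  alpha0 <- -0.25
  for (temp in list(rep(5, 20), seq(14, 3, length.out = 20))) {
    smr <- 8.04e13 * mass^alpha0 * exp(-0.65 / (8.62e-5 * (temp + 273.15)))
    moto <- 0.243 * (1 - exp(-0.0088 * smr))
    fit <- fit_alpha(mass, temp, moto, cv, refine = FALSE)
    expect_equal(fit$alpha_hat, alpha0, tolerance = 1e-12)
  }
})
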