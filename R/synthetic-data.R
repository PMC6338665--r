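#' Design of a synthetic temperature-controlled rearing experiment
#'
#' Truth values and noise structure emulating a four-temperature cod rearing
#' study: fish masses drawn log-uniformly within a range, SMR from the
#' Boltzmann-Arrhenius model, routine (fed) metabolism as a Gaussian
#' multiple of SMR, the metabolic carbon proportion from the saturating
#' calibration truth, and observable isotope values generated by inverting
#' the mixing model (d13C) and the thermometry line (d18O) with independent
#' Gaussian noise.
#'
#' Defaults mirror the reared-cod study conditions: temperatures 4/7/10/14
#' degC, masses 94-783 g, d13C_oto repeatability 0.17 permil, RMR multiplier
#' 1.55 +/- 0.0832, calibration truth C = 0.243, k = 0.0088, and a
#' normalisation constant of 8.04e13 (grams convention, alpha = -0.25).
#'
#' @param temperatures Nominal rearing temperatures (degC).
#' @param n_per_group Fish per temperature group (>= 2); either a scalar or
#'   one count per temperature (the reared-cod study used 11/15/19/18).
#'   Default 16.
#' @param mass_range Body mass range (g). Default c(94, 783).
#' @param true_B0 Normalisation constant (mass in g). Default 8.04e13.
#' @param true_alpha Mass-specific exponent. Default -0.25.
#' @param rmr_multiplier,rmr_multiplier_sd RMR_fed/SMR scaling.
#'   Defaults 1.55, 0.0832.
#' @param true_C,true_k Calibration truth. Defaults 0.243, 0.0088.
#' @param ends An [endmembers()] object; default uses the 7 degC tank
#'   values (DIC -0.18, diet -20.13).
#' @param d13C_oto_sd,d18O_oto_sd Observation noise SDs (permil).
#'   Defaults 0.17 and 0.28.
#' @param thermo_truth `"thermometry_model"` used to generate d18O from
#'   temperature; default T = 21.0 - 4.85 * d18O (fitted once to the
#'   four-group rearing means).
#' @param seed Optional integer seed stored in the design.
#' @return List of class `"rearing_design"`.
#' @export
rearing_design <- function(temperatures = c(4, 7, 10, 14),
                           n_per_group = 16,
                           mass_range = c(94, 783),
                           true_B0 = 8.04e13,
                           true_alpha = -0.25,
                           rmr_multiplier = 1.55,
                           rmr_multiplier_sd = 0.0832,
                           true_C = 0.243,
                           true_k = 0.0088,
                           ends = endmembers(-0.18, -20.13),
                           d13C_oto_sd = 0.17,
                           d18O_oto_sd = 0.28,
                           thermo_truth = thermometry_model(21.0, -4.85),
                           seed = NULL) {
  stopifnot(all(temperatures + 273.15 > 0), all(n_per_group >= 2),
            length(n_per_group) %in% c(1L, length(temperatures)),
            true_C > 0, true_C < 1, true_k > 0, true_B0 > 0,
            d13C_oto_sd >= 0, d18O_oto_sd >= 0, rmr_multiplier_sd >= 0,
            mass_range[1] > 0, mass_range[1] <= mass_range[2],
            inherits(ends, "endmembers"),
            inherits(thermo_truth, "thermometry_model"))
  design <- structure(
    list(temperatures = temperatures, n_per_group = n_per_group,
         mass_range = mass_range, true_B0 = true_B0,
         true_alpha = true_alpha,
         rmr_multiplier = rmr_multiplier,
         rmr_multiplier_sd = rmr_multiplier_sd,
         true_C = true_C, true_k = true_k, ends = ends,
         d13C_oto_sd = d13C_oto_sd, d18O_oto_sd = d18O_oto_sd,
         thermo_truth = thermo_truth, seed = seed),
    class = "rearing_design")
  # consistency of the truth values: maximal achievable M must stay below 1
  smr_max <- true_B0 * mass_range[1]^min(true_alpha, 0) *
    mass_range[2]^max(true_alpha, 0) *
    exp(-0.65 / (8.62e-5 * (max(temperatures) + 273.15)))
  rmr_max <- (rmr_multiplier + 4 * rmr_multiplier_sd) * smr_max
  if (true_C * (1 - exp(-true_k * rmr_max)) >= 1)
    stop("inconsistent truth values: maximal M_oto would reach 1")
  design
}

#' Simulate a rearing experiment
#'
#' Forward-composes the generative chain defined by a [rearing_design()].
#' Observables and the hidden truth are returned as two separate tables;
#' inference code must only ever see `$samples`.
#'
#' @param design A `"rearing_design"`.
#' @return List with `samples` (fish_id, group, temperature_nominal_C,
#'   mass_g, d13C_oto, d18O_oto, d13C_oto_sd) and `truth` (fish_id, smr,
#'   rmr, m_true, multiplier).
#' @export
simulate_rearing <- function(design) {
  stopifnot(inherits(design, "rearing_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n_g <- rep_len(design$n_per_group, length(design$temperatures))
  n <- sum(n_g)
  grp <- rep(design$temperatures, times = n_g)
  mass <- exp(stats::runif(n, log(design$mass_range[1]),
                           log(design$mass_range[2])))
  temp_K <- grp + 273.15
  smr <- design$true_B0 * mass^design$true_alpha *
    exp(-0.65 / (8.62e-5 * temp_K))
  mult <- stats::rnorm(n, design$rmr_multiplier, design$rmr_multiplier_sd)
  rmr <- mult * smr
  m_true <- design$true_C * (1 - exp(-design$true_k * rmr))
  ends <- design$ends
  d13C <- ends$d13C_DIC +
    (m_true - ends$epsilon) * (ends$d13C_diet - ends$d13C_DIC) +
    stats::rnorm(n, 0, design$d13C_oto_sd)
  th <- design$thermo_truth
  d18O <- (grp - th$intercept) / th$slope +
    stats::rnorm(n, 0, design$d18O_oto_sd)
  fish_id <- sprintf("F%03d", seq_len(n))
  list(
    samples = data.frame(
      fish_id = fish_id,
      group = factor(grp),
      temperature_nominal_C = grp,
      mass_g = mass,
      d13C_oto = d13C,
      d18O_oto = d18O,
      d13C_oto_sd = design$d13C_oto_sd),
    truth = data.frame(
      fish_id = fish_id, smr = smr, rmr = rmr,
      m_true = m_true, multiplier = mult))
}

#' Design of a synthetic age-structured wild population
#'
#' Each fish carries a trajectory of (mass, temperature, isotope) records
#' over ages, emulating sequential micromilled otolith samples. Growth
#' follows a cubed von Bertalanffy curve by default; the temperature rule
#' is any function of age. FMR truth is a fixed factorial scope times SMR,
#' so the population can be constructed to sit inside (or outside) the
#' power-budget bounds.
#'
#' @param n_fish Number of fish. Default 30.
#' @param ages Ages (years) at which each fish is sampled. Default 1:8.
#' @param mass_at_age Function age -> mass (g); must be positive and
#'   non-decreasing over `ages`. Default von Bertalanffy cubed with
#'   asymptotic mass 10 kg, K = 0.18, t0 = -0.5.
#' @param temperature_at_age Function age -> degC. Default constant 5.
#' @param fmr_scope FMR/SMR factorial scope truth. Default 2.0.
#' @param mass_cv Lognormal CV of individual mass about the growth curve.
#'   Default 0.1.
#' @inheritParams rearing_design
#' @return List of class `"wild_design"`.
#' @export
wild_design <- function(n_fish = 30, ages = 1:8,
                        mass_at_age = function(a)
                          10000 * (1 - exp(-0.18 * (a + 0.5)))^3,
                        temperature_at_age = function(a) rep(5, length(a)),
                        fmr_scope = 2.0,
                        true_B0 = 8.04e13, true_alpha = -0.25,
                        true_C = 0.243, true_k = 0.0088,
                        ends = endmembers(1, -19, 0.5, 3),
                        d13C_oto_sd = 0.17, d18O_oto_sd = 0.28,
                        thermo_truth = thermometry_model(21.0, -4.85),
                        mass_cv = 0.1, seed = NULL) {
  m <- mass_at_age(ages)
  stopifnot(all(m > 0), !is.unsorted(m), n_fish >= 1,
            fmr_scope > 0, true_C > 0, true_C < 1, true_k > 0,
            inherits(ends, "endmembers"))
  structure(
    list(n_fish = n_fish, ages = ages, mass_at_age = mass_at_age,
         temperature_at_age = temperature_at_age, fmr_scope = fmr_scope,
         true_B0 = true_B0, true_alpha = true_alpha,
         true_C = true_C, true_k = true_k, ends = ends,
         d13C_oto_sd = d13C_oto_sd, d18O_oto_sd = d18O_oto_sd,
         thermo_truth = thermo_truth, mass_cv = mass_cv, seed = seed),
    class = "wild_design")
}

#' Simulate an age-structured wild population
#'
#' @param design A [wild_design()].
#' @return List with `samples` (fish_id, age, mass_g, d13C_oto, d18O_oto,
#'   d13C_oto_sd) and `truth` (fish_id, age, temperature_C, smr, fmr,
#'   m_true).
#' @export
simulate_wild_population <- function(design) {
  stopifnot(inherits(design, "wild_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  rows <- truth <- vector("list", design$n_fish)
  base_mass <- design$mass_at_age(design$ages)
  temp_C <- design$temperature_at_age(design$ages)
  temp_C <- rep_len(temp_C, length(design$ages))
  for (f in seq_len(design$n_fish)) {
    id <- sprintf("W%03d", f)
    # one multiplicative size deviation per fish keeps mass non-decreasing
    mass <- base_mass * exp(stats::rnorm(1, 0, design$mass_cv))
    smr <- design$true_B0 * mass^design$true_alpha *
      exp(-0.65 / (8.62e-5 * (temp_C + 273.15)))
    fmr <- design$fmr_scope * smr
    m_true <- design$true_C * (1 - exp(-design$true_k * fmr))
    ends <- design$ends
    d13C <- ends$d13C_DIC +
      (m_true - ends$epsilon) * (ends$d13C_diet - ends$d13C_DIC) +
      stats::rnorm(length(mass), 0, design$d13C_oto_sd)
    th <- design$thermo_truth
    d18O <- (temp_C - th$intercept) / th$slope +
      stats::rnorm(length(mass), 0, design$d18O_oto_sd)
    rows[[f]] <- data.frame(
      fish_id = id, age = design$ages, mass_g = mass,
      d13C_oto = d13C, d18O_oto = d18O,
      d13C_oto_sd = design$d13C_oto_sd)
    truth[[f]] <- data.frame(
      fish_id = id, age = design$ages, temperature_C = temp_C,
      smr = smr, fmr = fmr, m_true = m_true)
  }
  list(samples = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Design of a synthetic multi-species compilation
#'
#' One row per species: species-mean mass, experienced temperature, and the
#' metabolic carbon proportion generated from the combined
#' calibration-Arrhenius model with optional species-level exponent
#' dispersion and Gaussian residual noise.
#'
#' @param n_species Number of species (>= 3). Default 76.
#' @param mass_range Species-mean mass range (g), drawn log-uniformly.
#'   Default 1 g to 100 kg.
#' @param temperature_range Experienced temperature range (degC), uniform.
#'   Default c(2, 28).
#' @param true_alpha Mass-specific exponent truth. Default -0.105.
#' @param alpha_sd Species-level SD of the exponent. Default 0.
#' @param residual_sd Gaussian residual SD on M_oto. Default 0.03, matching
#'   roughly 40% unexplained variance at an among-species spread of ~0.05.
#' @inheritParams rearing_design
#' @return List of class `"species_design"`.
#' @export
species_design <- function(n_species = 76,
                           mass_range = c(1, 1e5),
                           temperature_range = c(2, 28),
                           true_alpha = -0.105,
                           alpha_sd = 0,
                           residual_sd = 0.03,
                           true_B0 = 8.04e13,
                           true_C = 0.243, true_k = 0.0088,
                           ends = endmembers(1, -19, 0.5, 3),
                           seed = NULL) {
  stopifnot(n_species >= 3, residual_sd >= 0, alpha_sd >= 0,
            mass_range[1] > 0, true_C > 0, true_C < 1, true_k > 0,
            inherits(ends, "endmembers"))
  structure(
    list(n_species = n_species, mass_range = mass_range,
         temperature_range = temperature_range,
         true_alpha = true_alpha, alpha_sd = alpha_sd,
         residual_sd = residual_sd, true_B0 = true_B0,
         true_C = true_C, true_k = true_k, ends = ends, seed = seed),
    class = "species_design")
}

#' Simulate a species compilation
#'
#' @param design A [species_design()].
#' @return List with `samples` (species, mass_g, temperature_C, m_oto,
#'   d13C_oto derived via the endmembers) and `truth` (species, alpha,
#'   smr, m_true).
#' @export
simulate_species_compilation <- function(design) {
  stopifnot(inherits(design, "species_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_species
  mass <- exp(stats::runif(n, log(design$mass_range[1]),
                           log(design$mass_range[2])))
  temp_C <- stats::runif(n, design$temperature_range[1],
                         design$temperature_range[2])
  alpha <- stats::rnorm(n, design$true_alpha, design$alpha_sd)
  smr <- design$true_B0 * mass^alpha *
    exp(-0.65 / (8.62e-5 * (temp_C + 273.15)))
  m_true <- design$true_C * (1 - exp(-design$true_k * smr))
  m_obs <- m_true + stats::rnorm(n, 0, design$residual_sd)
  ends <- design$ends
  d13C <- ends$d13C_DIC +
    (m_obs - ends$epsilon) * (ends$d13C_diet - ends$d13C_DIC)
  sp <- sprintf("sp%03d", seq_len(n))
  list(
    samples = data.frame(
      species = sp, mass_g = mass, temperature_C = temp_C,
      m_oto = m_obs, d13C_oto = d13C),
    truth = data.frame(
      species = sp, alpha = alpha, smr = smr, m_true = m_true))
}
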