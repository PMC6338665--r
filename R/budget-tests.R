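#' Literature bounds on the components of the fish metabolic power budget
#'
#' Reference ranges used by the three power-budget validation tests:
#' specific dynamic action (SDA) is at most 0.4 of assimilated energy
#' (0.12 is a juvenile-cod average), activity metabolism in wild fish lies
#' between 0.3 and 3.9 times SMR, and the maximum metabolic rate factorial
#' scope (MMR/SMR) is 2.3-3.5. All interval endpoints are treated as
#' inclusive.
#'
#' @param sda_fraction_max Maximum SDA fraction of FMR. Default 0.4.
#' @param sda_fraction_juvenile Average juvenile SDA fraction. Default 0.12.
#' @param activity_smr_range Activity/SMR ratio range. Default c(0.3, 3.9).
#' @param mmr_scope_range MMR/SMR factorial scope range. Default c(2.3, 3.5).
#' @return List of class `"literature_bounds"`.
#' @export
literature_bounds <- function(sda_fraction_max = 0.4,
                              sda_fraction_juvenile = 0.12,
                              activity_smr_range = c(0.3, 3.9),
                              mmr_scope_range = c(2.3, 3.5)) {
  stopifnot(sda_fraction_max > 0, sda_fraction_max < 1,
            sda_fraction_juvenile > 0, sda_fraction_juvenile < 1,
            activity_smr_range[1] < activity_smr_range[2],
            mmr_scope_range[1] < mmr_scope_range[2])
  structure(list(sda_fraction_max = sda_fraction_max,
                 sda_fraction_juvenile = sda_fraction_juvenile,
                 activity_smr_range = activity_smr_range,
                 mmr_scope_range = mmr_scope_range),
            class = "literature_bounds")
}

#' Test 1: FMR exceeds the sum of SMR and maximal SDA
#'
#' The power budget requires FMR = SMR + SDA + activity with activity >= 0.
#' Taking SDA at its maximal fraction of FMR, the check is
#' `fmr * (1 - sda_fraction_max) > smr`; the margin is the left-hand side
#' minus SMR (the activity left over under maximal SDA).
#'
#' @param fmr,smr Field and standard metabolic rates (mg O2 kg-1 h-1),
#'   vectorised.
#' @param sda_fraction_max SDA as a maximal fraction of FMR. Default 0.4.
#' @return data.frame with `pass` and `margin`.
#' @export
test1_budget <- function(fmr, smr, sda_fraction_max = 0.4) {
  stopifnot(all(fmr >= 0), all(smr >= 0))
  margin <- fmr * (1 - sda_fraction_max) - smr
  data.frame(pass = margin > 0, margin = margin)
}

#' Test 2: activity metabolism falls in the published SMR-relative range
#'
#' Activity = FMR - SMR - SDA (with SDA a fraction of FMR); the ratio
#' activity/SMR should lie within the published range (inclusive).
#'
#' @inheritParams test1_budget
#' @param sda_fraction SDA fraction of FMR. Default 0.12 (juvenile average).
#' @param activity_smr_range Acceptable activity/SMR range.
#'   Default c(0.3, 3.9).
#' @return data.frame with `activity`, `ratio`, `in_range`, and
#'   `negative_activity` flag.
#' @export
test2_activity <- function(fmr, smr, sda_fraction = 0.12,
                           activity_smr_range = c(0.3, 3.9)) {
  stopifnot(all(fmr >= 0), all(smr > 0), sda_fraction >= 0, sda_fraction < 1)
  activity <- fmr - smr - sda_fraction * fmr
  ratio <- activity / smr
  data.frame(activity = activity, ratio = ratio,
             in_range = activity >= 0 &
               ratio >= activity_smr_range[1] &
               ratio <= activity_smr_range[2],
             negative_activity = activity < 0)
}

#' Test 3: FMR factorial scope stays below the MMR factorial scope
#'
#' Wild fish seldom operate at maximum metabolic rate, so FMR/SMR should not
#' exceed the published MMR/SMR scope (upper endpoint inclusive).
#'
#' @inheritParams test1_budget
#' @param mmr_scope_range Published MMR/SMR range. Default c(2.3, 3.5).
#' @return data.frame with `scope` and `pass`.
#' @export
test3_scope <- function(fmr, smr, mmr_scope_range = c(2.3, 3.5)) {
  if (any(smr <= 0)) stop("undefined factorial scope: SMR must be > 0")
  scope <- fmr / smr
  data.frame(scope = scope, pass = scope <= mmr_scope_range[2])
}

#' Run the full power-budget validation suite on a sample table
#'
#' Chains the whole proxy pipeline per fish: reconstruct temperature from
#' d18O, estimate M_oto from d13C with Monte Carlo propagation, invert the
#' calibration to FMR, predict SMR from mass and reconstructed temperature
#' with the supplied MTE model, and apply Tests 1-3. Per-fish Monte Carlo
#' pass fractions are reported alongside point-estimate flags.
#'
#' @param samples data.frame with columns `fish_id`, `d13C_oto`, `d18O_oto`,
#'   `mass_g` (and optionally `d13C_oto_sd`).
#' @param ends An [endmembers()] object.
#' @param curve A `"calibration_curve"`.
#' @param smr_model An [mte_model()] with a (user-supplied) fitted B0 for
#'   the study population; coefficients are never invented internally.
#' @param thermo A `"thermometry_model"`.
#' @param bounds A [literature_bounds()] object.
#' @param n_draws Monte Carlo draws per fish. Default 2000.
#' @param seed Optional integer seed (single seed governs the whole suite).
#' @return List of class `"budget_suite"` with `per_fish` (one row per fish:
#'   temperature, M_oto, FMR, SMR, SDA, activity, test flags and MC pass
#'   fractions) and `summary` (cohort pass rates).
#' @export
run_budget_suite <- function(samples, ends, curve, smr_model, thermo,
                             bounds = literature_bounds(),
                             n_draws = 2000, seed = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("fish_id", "d13C_oto", "d18O_oto", "mass_g") %in%
                  names(samples)),
            inherits(curve, "calibration_curve"),
            inherits(smr_model, "mte_model"),
            inherits(thermo, "thermometry_model"))
  if (!is.null(seed)) set.seed(seed)
  oto_sd <- if ("d13C_oto_sd" %in% names(samples)) samples$d13C_oto_sd
            else rep(0.17, nrow(samples))
  temp <- suppressWarnings(
    predict_temperature(thermo, samples$d18O_oto, n_draws = n_draws))
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    mo <- propagate_moto(samples$d13C_oto[i], ends, oto_sd[i],
                         n_draws = max(n_draws, 1000))
    fmr <- suppressWarnings(moto_to_fmr(mo, curve, n_draws = n_draws))
    smr <- mte_predict(smr_model, samples$mass_g[i], temp$mean_K[i])
    sda <- bounds$sda_fraction_juvenile * fmr$mean
    activity <- fmr$mean - smr - sda
    t1 <- test1_budget(fmr$mean, smr, bounds$sda_fraction_max)
    t2 <- test2_activity(fmr$mean, smr, bounds$sda_fraction_juvenile,
                         bounds$activity_smr_range)
    t3 <- test3_scope(fmr$mean, smr, bounds$mmr_scope_range)
    # MC pass fractions over FMR draws (SMR held at its point prediction)
    fdr <- stats::rnorm(n_draws, fmr$mean, fmr$sd)
    fdr <- fdr[fdr > 0]
    mc1 <- mean(fdr * (1 - bounds$sda_fraction_max) > smr)
    r2 <- (fdr * (1 - bounds$sda_fraction_juvenile) - smr) / smr
    mc2 <- mean(r2 >= bounds$activity_smr_range[1] &
                  r2 <= bounds$activity_smr_range[2])
    mc3 <- mean(fdr / smr <= bounds$mmr_scope_range[2])
    rows[[i]] <- data.frame(
      fish_id = samples$fish_id[i],
      mass_g = samples$mass_g[i],
      temperature_C = temp$mean_C[i],
      moto = mo$mean, moto_sd = mo$sd,
      fmr = fmr$mean, fmr_sd = fmr$sd,
      censored_frac = fmr$censored_frac,
      smr = smr, sda = sda, activity = activity,
      test1_pass = t1$pass, test1_margin = t1$margin,
      test2_ratio = t2$ratio, test2_pass = t2$in_range,
      test3_scope = t3$scope, test3_pass = t3$pass,
      test1_mc_frac = mc1, test2_mc_frac = mc2, test3_mc_frac = mc3)
  }
  per_fish <- do.call(rbind, rows)
  summary <- data.frame(
    n_fish = nrow(per_fish),
    test1_pass_rate = mean(per_fish$test1_pass),
    test2_pass_rate = mean(per_fish$test2_pass),
    test3_pass_rate = mean(per_fish$test3_pass),
    test1_mc_frac = mean(per_fish$test1_mc_frac),
    test2_mc_frac = mean(per_fish$test2_mc_frac),
    test3_mc_frac = mean(per_fish$test3_mc_frac),
    mean_fmr = mean(per_fish$fmr),
    mean_scope = mean(per_fish$test3_scope))
  structure(list(per_fish = per_fish, summary = summary),
            class = "budget_suite")
}

#' @export
print.budget_suite <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Power-budget suite over %d fish\n", s$n_fish))
  cat(sprintf("  Test 1 (budget)  : %.0f%% pass\n", 100 * s$test1_pass_rate))
  cat(sprintf("  Test 2 (activity): %.0f%% pass\n", 100 * s$test2_pass_rate))
  cat(sprintf("  Test 3 (scope)   : %.0f%% pass (mean scope %.2f)\n",
              100 * s$test3_pass_rate, s$mean_scope))
  invisible(x)
}
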