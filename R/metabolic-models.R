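#' Boltzmann-Arrhenius (MTE) model of standard metabolic rate
#'
#' Metabolic theory of ecology: mass-specific SMR =
#' `B0 * mass^alpha * exp(-E / (kB * T_K))` with activation energy E = 0.65 eV
#' and Boltzmann constant kB = 8.62e-5 eV/K. The mass exponent uses the
#' mass-specific convention (default -0.25; the whole-organism exponent is
#' `alpha + 1`). `B0` carries the units: with mass in grams and output in
#' mg O2 per kg per h, a cod-like value is ~8e13. Note that a fitted B0 is
#' not portable across mass-unit or alpha conventions: changing mass units
#' from kg to g rescales B0 by `1000^(-alpha)`.
#'
#' @param B0 Normalisation constant (> 0); units set the output scale.
#' @param alpha Mass exponent, mass-specific convention. Default -0.25
#'   (theoretical); -0.21 is a fish-specific empirical alternative.
#' @param activation_energy Activation energy in eV, default 0.65.
#' @param boltzmann Boltzmann constant in eV/K, default 8.62e-5.
#' @return Object of class `"mte_model"`.
#' @export
mte_model <- function(B0, alpha = -0.25,
                      activation_energy = 0.65, boltzmann = 8.62e-5) {
  stopifnot(is.numeric(B0), B0 > 0, is.numeric(alpha),
            activation_energy > 0, boltzmann > 0)
  structure(
    list(B0 = B0, alpha = alpha,
         activation_energy = activation_energy, boltzmann = boltzmann,
         convention = "mass-specific"),
    class = "mte_model")
}

#' @export
print.mte_model <- function(x, ...) {
  cat(sprintf(
    "MTE model: SMR = %.4g * mass^%.3f * exp(-%.2f/(%.3g * T_K))  [%s]\n",
    x$B0, x$alpha, x$activation_energy, x$boltzmann, x$convention))
  invisible(x)
}

#' Predict mass-specific metabolic rate from mass and temperature
#'
#' @param model An [mte_model()].
#' @param mass Body mass (g), > 0, vectorised.
#' @param temp_K Absolute temperature (K), > 0, vectorised.
#' @return Mass-specific metabolic rate (mg O2 kg-1 h-1 when B0 is in the
#'   package's standard units).
#' @export
mte_predict <- function(model, mass, temp_K) {
  stopifnot(inherits(model, "mte_model"), all(mass > 0), all(temp_K > 0))
  model$B0 * mass^model$alpha *
    exp(-model$activation_energy / (model$boltzmann * temp_K))
}

#' Fit the MTE normalisation constant to measured metabolic rates
#'
#' With alpha, activation energy and kB held fixed, the MTE model is linear
#' through the origin in the composite predictor
#' `x = mass^alpha * exp(-E/(kB*T))`; B0 is estimated by origin-constrained
#' OLS of measured SMR on x (a slope-only regression).
#'
#' @param mass Body masses (g).
#' @param temp_K Temperatures (K).
#' @param smr Measured standard metabolic rates (mg O2 kg-1 h-1).
#' @param alpha Mass exponent held fixed during the fit. Default -0.25.
#' @param activation_energy,boltzmann As in [mte_model()].
#' @return List of class `"b0_fit"`: `model` (an `mte_model` with fitted B0),
#'   `B0`, `se`, `t`, `p`, `r_squared` (origin-constrained convention,
#'   1 - RSS/sum(y^2)), `n`, and the underlying `lm` fit.
#' @export
fit_B0 <- function(mass, temp_K, smr, alpha = -0.25,
                   activation_energy = 0.65, boltzmann = 8.62e-5) {
  stopifnot(length(mass) == length(smr), length(temp_K) == length(smr))
  if (length(smr) < 3) stop("need >= 3 measurements to fit B0")
  x <- mass^alpha * exp(-activation_energy / (boltzmann * temp_K))
  if (max(x) - min(x) <= .Machine$double.eps * max(abs(x)))
    if (stats::var(smr) > 0)
      warning("all MTE predictor values identical; B0 weakly identified")
  fit <- stats::lm(smr ~ 0 + x)
  sm <- summary(fit)
  B0 <- unname(stats::coef(fit)[1])
  if (!is.finite(B0) || B0 <= 0)
    warning("fitted B0 is non-positive; check data and alpha convention")
  structure(
    list(model = mte_model(B0 = abs(B0), alpha = alpha,
                           activation_energy = activation_energy,
                           boltzmann = boltzmann),
         B0 = B0,
         se = sm$coefficients[1, 2],
         t = sm$coefficients[1, 3],
         p = sm$coefficients[1, 4],
         r_squared = sm$r.squared,
         n = length(smr),
         fit = fit),
    class = "b0_fit")
}

#' @export
print.b0_fit <- function(x, ...) {
  cat(sprintf("B0 = %.4g (se %.3g), t = %.3g, R^2 = %.3f, n = %d\n",
              x$B0, x$se, x$t, x$r_squared, x$n))
  invisible(x)
}

#' Scale standard metabolic rate to routine (fed) metabolic rate
#'
#' In ad-libitum laboratory conditions field metabolic rate is close to the
#' routine metabolic rate of fed fish, modelled as a multiple of SMR with a
#' Gaussian multiplier (default 1.55 +/- 0.0832).
#'
#' @param smr SMR value(s) (mg O2 kg-1 h-1).
#' @param multiplier Mean RMR/SMR multiplier, > 1. Default 1.55.
#' @param multiplier_sd SD of the multiplier. Default 0.0832.
#' @param n_draws Draws per SMR value; if `multiplier_sd` is 0 the result is
#'   the deterministic multiple. Default 10000.
#' @param seed Optional integer seed.
#' @return List with `mean`, `sd` (vectors matching `smr`) and, for scalar
#'   input, the vector of `draws`.
#' @export
smr_to_rmr <- function(smr, multiplier = 1.55, multiplier_sd = 0.0832,
                       n_draws = 10000, seed = NULL) {
  stopifnot(all(smr >= 0), multiplier > 1, multiplier_sd >= 0)
  if (multiplier_sd == 0)
    return(list(mean = multiplier * smr, sd = rep(0, length(smr)),
                draws = if (length(smr) == 1L) rep(multiplier * smr, n_draws)))
  if (!is.null(seed)) set.seed(seed)
  mult <- stats::rnorm(n_draws, multiplier, multiplier_sd)
  out <- list(mean = multiplier * smr, sd = multiplier_sd * smr)
  if (length(smr) == 1L) out$draws <- mult * smr
  out
}

#' Standard metabolic rate from swim-tunnel respirometry
#'
#' Fits an exponential speed-metabolism model `MO2 = a * exp(b * speed)` and
#' extrapolates to zero swimming speed; the intercept `a` is the SMR
#' estimate. The default fit is OLS on log-transformed MO2 (so the model is
#' linear in log space); `method = "nls"` refits by direct nonlinear least
#' squares on the original scale.
#'
#' @param speed Swimming speeds (body lengths per second), >= 0.
#' @param mo2 Oxygen consumption (mg O2 kg-1 h-1), > 0 (log-transform).
#' @param excluded Logical vector flagging loops to drop (e.g. recorded
#'   unwanted behaviour); flags are honoured as data, never re-derived.
#' @param method `"log-ols"` (default) or `"nls"`.
#' @return List of class `"smr_fit"`: `smr` (rate at speed 0), `b` (speed
#'   coefficient), `method`, `n`, and the model fit object.
#' @export
smr_from_swim <- function(speed, mo2, excluded = FALSE,
                          method = c("log-ols", "nls")) {
  method <- match.arg(method)
  stopifnot(length(speed) == length(mo2))
  excluded <- rep_len(excluded, length(speed))
  speed <- speed[!excluded]; mo2 <- mo2[!excluded]
  if (any(speed < 0)) stop("swimming speeds must be >= 0")
  if (length(speed) < 3) stop("need >= 3 non-excluded (speed, MO2) pairs")
  if (any(mo2 <= 0)) stop("MO2 must be positive (log-transform undefined)")
  if (method == "log-ols") {
    fit <- stats::lm(log(mo2) ~ speed)
    a <- exp(unname(stats::coef(fit)[1]))
    b <- unname(stats::coef(fit)[2])
  } else {
    start <- list(a = exp(unname(stats::coef(stats::lm(log(mo2) ~ speed))[1])),
                  b = unname(stats::coef(stats::lm(log(mo2) ~ speed))[2]))
    fit <- minpack.lm::nlsLM(mo2 ~ a * exp(b * speed), start = start)
    a <- unname(stats::coef(fit)["a"])
    b <- unname(stats::coef(fit)["b"])
  }
  structure(list(smr = a, b = b, method = method, n = length(speed), fit = fit),
            class = "smr_fit")
}

#' @export
print.smr_fit <- function(x, ...) {
  cat(sprintf("SMR = %.2f mg O2 kg-1 h-1 (exponential %s fit, b = %.3f, n = %d)\n",
              x$smr, x$method, x$b, x$n))
  invisible(x)
}
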