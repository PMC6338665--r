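#' Construct an aragonite oxygen-isotope thermometry model
#'
#' Linear relationship T(degC) = intercept + slope * d18O_oto. Use this
#' constructor to supply coefficients from a published aragonite
#' fractionation study (e.g. for wild fish where no in-experiment
#' calibration exists); no published coefficients are hard-coded, the user
#' must transcribe and cite them. [fit_thermometry()] builds the same object
#' from rearing-experiment data.
#'
#' @param intercept,slope Coefficients of the T-on-d18O line (slope must be
#'   nonzero; for marine aragonite the slope is negative).
#' @param residual_sd Residual SD of temperature about the line (degC).
#' @param coef_vcov Optional 2x2 variance-covariance matrix of
#'   (intercept, slope); defaults to zero (coefficients treated as known).
#' @param d18O_range Optional range of d18O values over which the line is
#'   considered calibrated; predictions outside it are flagged.
#' @param provenance `"published"` or `"fitted"`.
#' @return Object of class `"thermometry_model"`.
#' @export
thermometry_model <- function(intercept, slope, residual_sd = 0,
                              coef_vcov = matrix(0, 2, 2),
                              d18O_range = c(-Inf, Inf),
                              provenance = "published") {
  stopifnot(is.numeric(intercept), is.numeric(slope), slope != 0,
            residual_sd >= 0, all(dim(coef_vcov) == c(2, 2)))
  structure(
    list(intercept = unname(intercept), slope = unname(slope),
         residual_sd = residual_sd, coef_vcov = unname(coef_vcov),
         d18O_range = range(d18O_range), provenance = provenance),
    class = "thermometry_model")
}

#' @export
print.thermometry_model <- function(x, ...) {
  cat(sprintf("Thermometry model (%s): T = %.3f %+.3f * d18O  (residual sd %.3f degC)\n",
              x$provenance, x$intercept, x$slope, x$residual_sd))
  invisible(x)
}

#' Fit a temperature ~ d18O thermometry model by OLS
#'
#' Regresses known rearing temperatures on measured otolith d18O values
#' (temperature on the left-hand side, matching how the model is later used
#' for prediction). Requires at least two distinct temperature levels.
#'
#' @param temperature_C Known temperatures (degC), one per otolith sample.
#' @param d18O Otolith d18O values (permil VPDB), same length.
#' @return A `"thermometry_model"` with provenance `"fitted"`, carrying the
#'   coefficient covariance and residual SD for Monte Carlo prediction.
#' @export
fit_thermometry <- function(temperature_C, d18O) {
  stopifnot(length(temperature_C) == length(d18O), length(d18O) >= 2)
  if (length(unique(temperature_C)) < 2)
    stop("thermometry unidentifiable: need >= 2 distinct temperature levels")
  fit <- stats::lm(temperature_C ~ d18O)
  cf <- stats::coef(fit)
  if (!is.finite(cf[2]) || cf[2] == 0)
    stop("thermometry unidentifiable: d18O values are collinear/constant")
  rsd <- if (stats::df.residual(fit) > 0) summary(fit)$sigma else 0
  thermometry_model(intercept = cf[1], slope = cf[2],
                    residual_sd = rsd,
                    coef_vcov = stats::vcov(fit),
                    d18O_range = range(d18O),
                    provenance = "fitted")
}

#' Predict experienced temperature from otolith d18O
#'
#' Point prediction from the thermometry line, with Monte Carlo uncertainty
#' combining coefficient error (draws from the coefficient covariance) and
#' residual scatter; both sources are separately switchable. Kelvin
#' conversion (T + 273.15) is returned for downstream Arrhenius use.
#'
#' @param model A `"thermometry_model"`.
#' @param d18O d18O values (permil VPDB), vectorised.
#' @param n_draws Monte Carlo draws per value. Default 10000.
#' @param seed Optional integer seed.
#' @param coef_error,residual_error Logicals: include coefficient
#'   uncertainty / residual scatter in the draws. Both default TRUE.
#' @return data.frame with columns `d18O`, `mean_C`, `sd_C`, `mean_K`,
#'   `extrapolated` (outside the calibrated d18O range).
#' @export
predict_temperature <- function(model, d18O, n_draws = 10000, seed = NULL,
                                coef_error = TRUE, residual_error = TRUE) {
  stopifnot(inherits(model, "thermometry_model"), is.numeric(d18O))
  if (!is.null(seed)) set.seed(seed)
  extrap <- d18O < model$d18O_range[1] | d18O > model$d18O_range[2]
  if (any(extrap))
    warning(sprintf("%d d18O value(s) outside the calibrated range [%.2f, %.2f]",
                    sum(extrap), model$d18O_range[1], model$d18O_range[2]))
  point <- model$intercept + model$slope * d18O
  use_coef <- coef_error && any(model$coef_vcov != 0)
  use_res <- residual_error && model$residual_sd > 0
  if (!use_coef && !use_res) {
    sd_C <- rep(0, length(d18O))
    mean_C <- point
  } else {
    # draw coefficients once, shared across samples (they are one fit)
    if (use_coef) {
      ch <- chol(model$coef_vcov + diag(1e-18, 2))
      z <- matrix(stats::rnorm(2 * n_draws), ncol = 2) %*% ch
      a <- model$intercept + z[, 1]
      b <- model$slope + z[, 2]
    } else {
      a <- rep(model$intercept, n_draws)
      b <- rep(model$slope, n_draws)
    }
    mean_C <- sd_C <- numeric(length(d18O))
    for (i in seq_along(d18O)) {
      t_draw <- a + b * d18O[i]
      if (use_res) t_draw <- t_draw + stats::rnorm(n_draws, 0, model$residual_sd)
      mean_C[i] <- mean(t_draw)
      sd_C[i] <- stats::sd(t_draw)
    }
  }
  data.frame(d18O = d18O, mean_C = mean_C, sd_C = sd_C,
             mean_K = mean_C + 273.15, extrapolated = extrap)
}
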