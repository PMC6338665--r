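#' Carbon isotope endmembers for the otolith mixing model
#'
#' Bundles the two carbon sources that mix in fish blood and hence in otolith
#' aragonite: dissolved inorganic carbon (DIC) of the ambient water (the
#' isotopically heavy endmember) and metabolic carbon respired from the diet
#' (the light endmember). Delta values are permil vs VPDB.
#'
#' @param d13C_DIC Mean delta13C of water DIC (permil VPDB). May be given as a
#'   vector of repeated water samplings, which are averaged; their spread
#'   contributes to `d13C_DIC_sd` when that is not supplied.
#' @param d13C_diet Mean delta13C of the diet (permil VPDB).
#' @param d13C_DIC_sd Standard deviation of the DIC endmember (permil).
#'   Default 0.03.
#' @param d13C_diet_sd Standard deviation of the diet endmember (permil).
#'   Default 0.86.
#' @param epsilon Net isotopic fractionation during carbon exchange between
#'   DIC, blood and endolymph, applied as an additive term to the mixing
#'   proportion. Default 0.
#' @return An object of class `"endmembers"`.
#' @examples
#' em <- endmembers(d13C_DIC = c(-0.15, -0.22), d13C_diet = -19.96)
#' compute_moto(-2.23, em)
#' @export
endmembers <- function(d13C_DIC, d13C_diet,
                       d13C_DIC_sd = 0.03, d13C_diet_sd = 0.86,
                       epsilon = 0) {
  stopifnot(is.numeric(d13C_DIC), is.numeric(d13C_diet),
            length(d13C_diet) == 1L)
  if (length(d13C_DIC) > 1L) {
    if (missing(d13C_DIC_sd)) d13C_DIC_sd <- stats::sd(d13C_DIC)
    d13C_DIC <- mean(d13C_DIC)
  }
  if (!all(is.finite(c(d13C_DIC, d13C_diet))))
    stop("endmember delta values must be finite")
  if (d13C_DIC == d13C_diet)
    stop("undefined mixture: DIC and diet endmembers are equal")
  if (d13C_DIC_sd < 0 || d13C_diet_sd < 0)
    stop("endmember SDs must be >= 0")
  structure(
    list(d13C_DIC = d13C_DIC, d13C_DIC_sd = d13C_DIC_sd,
         d13C_diet = d13C_diet, d13C_diet_sd = d13C_diet_sd,
         epsilon = epsilon),
    class = "endmembers")
}

#' @export
print.endmembers <- function(x, ...) {
  cat("Carbon isotope endmembers (permil VPDB)\n")
  cat(sprintf("  DIC : %6.2f (sd %.3f)\n", x$d13C_DIC, x$d13C_DIC_sd))
  cat(sprintf("  diet: %6.2f (sd %.3f)\n", x$d13C_diet, x$d13C_diet_sd))
  cat(sprintf("  epsilon: %g\n", x$epsilon))
  invisible(x)
}

#' Proportion of metabolically derived carbon in otolith aragonite
#'
#' Two-endmember mixing: the otolith delta13C value is a weighted average of
#' the DIC and diet (metabolic) endmembers, so the metabolic proportion is
#'
#' \deqn{M_{oto} = \frac{\delta^{13}C_{oto} - \delta^{13}C_{DIC}}
#'                      {\delta^{13}C_{diet} - \delta^{13}C_{DIC}} + \varepsilon}
#'
#' The value is returned unclipped: estimates outside \[0, 1\] are physically
#' impossible under the mixing model and signal endmember misspecification,
#' but they are preserved for diagnostics (use [propagate_moto()] or
#' [run_pipeline()] for validity flagging; clipping happens only at
#' calibration inversion).
#'
#' @param d13C_oto Otolith delta13C values (permil VPDB), vectorised.
#' @param ends An [endmembers()] object.
#' @return Numeric vector of mixing proportions (unclipped).
#' @export
compute_moto <- function(d13C_oto, ends) {
  stopifnot(inherits(ends, "endmembers"), is.numeric(d13C_oto))
  (d13C_oto - ends$d13C_DIC) / (ends$d13C_diet - ends$d13C_DIC) + ends$epsilon
}

#' Monte Carlo uncertainty of the metabolic carbon proportion
#'
#' Propagates measurement uncertainty in the otolith value and in both
#' endmembers through the mixing model by independent Gaussian resampling.
#'
#' @param d13C_oto Otolith delta13C mean (permil VPDB), scalar.
#' @param ends An [endmembers()] object (supplies endmember means and SDs).
#' @param d13C_oto_sd SD of the otolith value; default 0.17 permil, the
#'   intra-otolith repeatability typical of micromilled aragonite samples.
#' @param n_draws Number of Monte Carlo draws, >= 1000. Default 10000.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"moto_estimate"`: a list with `mean`, `sd`,
#'   `n_draws` (valid draws retained), `n_excluded`, `in_range` (logical,
#'   point estimate within \[0,1\]) and the point estimate `point`.
#' @examples
#' em <- endmembers(c(-0.15, -0.22), -19.96, 0.03, 0.86)
#' propagate_moto(-2.23, em, n_draws = 5000, seed = 1)
#' @export
propagate_moto <- function(d13C_oto, ends, d13C_oto_sd = 0.17,
                           n_draws = 10000, seed = NULL) {
  stopifnot(inherits(ends, "endmembers"), length(d13C_oto) == 1L,
            d13C_oto_sd >= 0)
  if (n_draws < 1000)
    stop("n_draws must be >= 1000 for a stable Monte Carlo SD")
  if (!is.null(seed)) set.seed(seed)
  oto <- stats::rnorm(n_draws, d13C_oto, d13C_oto_sd)
  dic <- stats::rnorm(n_draws, ends$d13C_DIC, ends$d13C_DIC_sd)
  diet <- stats::rnorm(n_draws, ends$d13C_diet, ends$d13C_diet_sd)
  m <- (oto - dic) / (diet - dic) + ends$epsilon
  keep <- is.finite(m)
  n_excl <- sum(!keep)
  if (n_excl > 0.01 * n_draws)
    warning(sprintf("%d of %d Monte Carlo draws non-finite and excluded",
                    n_excl, n_draws))
  m <- m[keep]
  point <- compute_moto(d13C_oto, ends)
  structure(
    list(mean = mean(m),
         sd = if (length(m) > 1L) stats::sd(m) else 0,
         point = point,
         n_draws = length(m), n_excluded = n_excl,
         in_range = point >= 0 && point <= 1),
    class = "moto_estimate")
}

#' @export
print.moto_estimate <- function(x, ...) {
  cat(sprintf("M_oto = %.4f (MC sd %.4f, n = %d draws%s)\n",
              x$mean, x$sd, x$n_draws,
              if (x$in_range) "" else "; OUT OF [0,1]"))
  invisible(x)
}

#' First-order (delta-method) SD of the metabolic carbon proportion
#'
#' Analytic companion to [propagate_moto()]: linearises the mixing ratio in
#' the three delta inputs and combines their variances. Useful as an
#' independent check on the Monte Carlo engine and as a fast approximation.
#'
#' @inheritParams propagate_moto
#' @return Approximate standard deviation of the mixing proportion.
#' @export
moto_sd_delta_method <- function(d13C_oto, ends, d13C_oto_sd = 0.17) {
  stopifnot(inherits(ends, "endmembers"))
  den <- ends$d13C_diet - ends$d13C_DIC
  m <- (d13C_oto - ends$d13C_DIC) / den
  g_oto <- 1 / den
  g_diet <- -m / den
  g_dic <- (m - 1) / den
  sqrt((g_oto * d13C_oto_sd)^2 +
       (g_diet * ends$d13C_diet_sd)^2 +
       (g_dic * ends$d13C_DIC_sd)^2)
}
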