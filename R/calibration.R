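#' Fit the saturating calibration between M_oto and oxygen consumption
#'
#' The metabolic carbon proportion saturates with oxygen consumption because
#' it is bounded above:
#'
#' \deqn{M_{oto} = C (1 - e^{-k \cdot O_2})}
#'
#' where `C` is the upper bound (asymptote, a proportion) and `k` the rate
#' constant (per mg O2 kg-1 h-1). The central estimate is a bounded
#' Levenberg-Marquardt nonlinear least-squares fit; uncertainty in both x
#' (oxygen consumption) and y (M_oto) is propagated by Monte Carlo: each
#' repeat perturbs x and y within their stated SDs, refits, and the ensemble
#' of (C, k) pairs summarises the joint uncertainty.
#'
#' @param o2 Oxygen consumption values (mg O2 kg-1 h-1).
#' @param moto M_oto values (proportions), same length.
#' @param o2_sd,moto_sd Per-observation SDs (scalars are recycled); 0 means
#'   treated as exact in the resampling.
#' @param n_mc Monte Carlo refits for the ensemble. Default 10000.
#' @param seed Optional integer seed.
#' @return Object of class `"calibration_curve"`: `C`, `k`, `se_C`, `se_k`
#'   (NLS standard errors), `ensemble` (matrix of MC (C, k) pairs),
#'   `ensemble_mean`, `ensemble_sd`, `n_fit`, `n_failed`, `seed`.
#' @examples
#' o2 <- seq(20, 200, length.out = 10)
#' m <- 0.243 * (1 - exp(-0.0088 * o2))
#' fit_calibration(o2, m, n_mc = 1000, seed = 1)
#' @export
fit_calibration <- function(o2, moto, o2_sd = 0, moto_sd = 0,
                            n_mc = 10000, seed = NULL) {
  stopifnot(length(o2) == length(moto))
  if (length(unique(o2)) < 3)
    stop("need >= 3 pairs spanning distinct oxygen-consumption values")
  o2_sd <- rep_len(o2_sd, length(o2))
  moto_sd <- rep_len(moto_sd, length(moto))
  central <- .fit_sat_curve(o2, moto)
  if (is.null(central))
    stop("calibration fit did not converge; check data and starting values")
  cf <- stats::coef(central)
  if (cf["C"] > 1)
    warning("fitted asymptote C exceeds 1; flagged, not truncated")
  ses <- tryCatch(summary(central)$coefficients[, 2],
                  error = function(e) c(C = NA_real_, k = NA_real_))
  ens <- NULL
  n_failed <- 0L
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    ens <- matrix(NA_real_, n_mc, 2, dimnames = list(NULL, c("C", "k")))
    for (i in seq_len(n_mc)) {
      xi <- stats::rnorm(length(o2), o2, o2_sd)
      yi <- stats::rnorm(length(moto), moto, moto_sd)
      fi <- .fit_sat_curve(xi, yi)
      if (!is.null(fi)) ens[i, ] <- stats::coef(fi)
    }
    ok <- stats::complete.cases(ens)
    n_failed <- sum(!ok)
    ens <- ens[ok, , drop = FALSE]
    if (n_failed > 0.05 * n_mc)
      warning(sprintf("%d of %d Monte Carlo refits failed to converge",
                      n_failed, n_mc))
  }
  structure(
    list(C = unname(cf["C"]), k = unname(cf["k"]),
         se_C = unname(ses[1]), se_k = unname(ses[2]),
         ensemble = ens,
         ensemble_mean = if (!is.null(ens)) colMeans(ens),
         ensemble_sd = if (!is.null(ens)) apply(ens, 2, stats::sd),
         n_fit = length(o2), n_failed = n_failed, seed = seed,
         fit = central),
    class = "calibration_curve")
}

# bounded LM fit of M = C(1 - exp(-k*o2)); NULL on failure
.fit_sat_curve <- function(o2, moto) {
  start <- list(C = min(max(moto) * 1.2, 0.99), k = 1 / mean(abs(o2)))
  if (!is.finite(start$C) || start$C <= 0) start$C <- 0.5
  tryCatch(
    minpack.lm::nlsLM(moto ~ C * (1 - exp(-k * o2)),
                      start = start,
                      lower = c(C = 1e-8, k = 1e-12),
                      upper = c(C = 5, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Shorthand constructor for a known calibration curve
#'
#' Builds a `"calibration_curve"` from given (C, k) without data, e.g. to use
#' published coefficients or generator truth downstream.
#'
#' @param C Asymptote in (0, 1].
#' @param k Rate constant > 0.
#' @param se_C,se_k Optional standard errors (default 0: treated as exact).
#' @return Object of class `"calibration_curve"` (no ensemble).
#' @export
calibration_curve <- function(C, k, se_C = 0, se_k = 0) {
  stopifnot(C > 0, k > 0)
  structure(list(C = C, k = k, se_C = se_C, se_k = se_k,
                 ensemble = NULL, ensemble_mean = NULL, ensemble_sd = NULL,
                 n_fit = 0L, n_failed = 0L, seed = NULL, fit = NULL),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Saturating calibration: M = C(1 - exp(-k * O2))\n"))
  cat(sprintf("  C = %.4f (se %.4g), k = %.4g (se %.4g), n = %d\n",
              x$C, x$se_C, x$k, x$se_k, x$n_fit))
  if (!is.null(x$ensemble))
    cat(sprintf("  MC ensemble: %d fits, sd(C) = %.4g, sd(k) = %.4g\n",
                nrow(x$ensemble), x$ensemble_sd[1], x$ensemble_sd[2]))
  invisible(x)
}

#' Forward evaluation of the calibration curve
#'
#' @param curve A `"calibration_curve"`.
#' @param o2 Oxygen consumption values (mg O2 kg-1 h-1).
#' @return Predicted M_oto values.
#' @export
calibration_predict <- function(curve, o2) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$C * (1 - exp(-curve$k * o2))
}

#' Invert the calibration: oxygen consumption from the metabolic proportion
#'
#' Solves M = C(1 - exp(-k*O2)) for O2: `O2 = -log(1 - M/C) / k`. With
#' uncertain inputs, each Monte Carlo draw samples M (Gaussian) and a (C, k)
#' pair from the calibration ensemble (or Gaussian around the point
#' estimates when no ensemble is present). Draws with M >= C cannot be
#' inverted; they are censored, counted, and excluded from the summary.
#'
#' @param moto A `"moto_estimate"` from [propagate_moto()], or a single
#'   numeric M_oto value (then `moto_sd` supplies its SD).
#' @param curve A `"calibration_curve"`.
#' @param moto_sd SD used when `moto` is numeric. Default 0.
#' @param n_draws Monte Carlo draws. Default 10000.
#' @param seed Optional integer seed.
#' @return Object of class `"fmr_estimate"`: `mean`, `sd`
#'   (mg O2 kg-1 h-1, over uncensored draws), `point` (deterministic
#'   inversion of the point inputs, NA if M >= C), `censored_frac`,
#'   `unreliable` (TRUE when more than half the draws are censored),
#'   `n_draws`.
#' @examples
#' cv <- calibration_curve(C = 0.243, k = 0.0088)
#' moto_to_fmr(0.10, cv)$point   # about 60.3
#' @export
moto_to_fmr <- function(moto, curve, moto_sd = 0, n_draws = 10000,
                        seed = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (inherits(moto, "moto_estimate")) {
    m_mean <- moto$mean; m_sd <- moto$sd
  } else {
    stopifnot(is.numeric(moto), length(moto) == 1L)
    m_mean <- moto; m_sd <- moto_sd
  }
  point <- if (m_mean < curve$C) -log(1 - m_mean / curve$C) / curve$k else NA_real_
  stochastic <- m_sd > 0 || !is.null(curve$ensemble) ||
    (!is.null(curve$se_C) && (curve$se_C > 0 || curve$se_k > 0))
  if (!stochastic) {
    return(structure(
      list(mean = point, sd = 0, point = point,
           censored_frac = as.numeric(is.na(point)),
           unreliable = is.na(point), n_draws = n_draws),
      class = "fmr_estimate"))
  }
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rnorm(n_draws, m_mean, m_sd)
  if (!is.null(curve$ensemble) && nrow(curve$ensemble) > 0) {
    idx <- sample.int(nrow(curve$ensemble), n_draws, replace = TRUE)
    Cs <- curve$ensemble[idx, 1]; ks <- curve$ensemble[idx, 2]
  } else {
    Cs <- stats::rnorm(n_draws, curve$C, curve$se_C)
    ks <- stats::rnorm(n_draws, curve$k, curve$se_k)
  }
  valid <- m < Cs & m > 0 & Cs > 0 & ks > 0
  o2 <- -log(1 - m[valid] / Cs[valid]) / ks[valid]
  cens <- 1 - sum(valid) / n_draws
  if (cens > 0.5)
    warning(sprintf("FMR estimate unreliable: %.0f%% of draws censored (M >= C)",
                    100 * cens))
  structure(
    list(mean = if (sum(valid)) mean(o2) else NA_real_,
         sd = if (sum(valid) > 1) stats::sd(o2) else 0,
         point = point,
         censored_frac = cens,
         unreliable = cens > 0.5,
         n_draws = n_draws),
    class = "fmr_estimate")
}

#' @export
print.fmr_estimate <- function(x, ...) {
  cat(sprintf("FMR = %.1f mg O2 kg-1 h-1 (MC sd %.2f, %.1f%% censored%s)\n",
              x$mean, x$sd, 100 * x$censored_frac,
              if (x$unreliable) "; UNRELIABLE" else ""))
  invisible(x)
}

#' Per-sample FMR estimates with an uncertainty decomposition
#'
#' Runs the mixing model and calibration inversion per sample and partitions
#' the FMR variance among the three uncertainty sources (otolith d13C,
#' endmembers, calibration curve) by switching one source on at a time; the
#' reported fractions are normalised to sum to 1.
#'
#' @param d13C_oto Vector of otolith d13C values.
#' @param ends An [endmembers()] object.
#' @param curve A `"calibration_curve"`.
#' @param d13C_oto_sd Otolith SD (scalar or vector). Default 0.17.
#' @param n_draws Draws per source per sample. Default 5000.
#' @param seed Optional integer seed.
#' @return data.frame with per-sample FMR mean and SD and the variance
#'   fractions `frac_oto`, `frac_endmembers`, `frac_curve`.
#' @export
fmr_precision_report <- function(d13C_oto, ends, curve,
                                 d13C_oto_sd = 0.17, n_draws = 5000,
                                 seed = NULL) {
  stopifnot(inherits(ends, "endmembers"), inherits(curve, "calibration_curve"))
  if (!is.null(seed)) set.seed(seed)
  d13C_oto_sd <- rep_len(d13C_oto_sd, length(d13C_oto))
  ends0 <- ends; ends0$d13C_DIC_sd <- 0; ends0$d13C_diet_sd <- 0
  one <- function(oto, oto_sd) {
    full <- moto_to_fmr(propagate_moto(oto, ends, oto_sd, max(n_draws, 1000)),
                        curve, n_draws = n_draws)
    v_oto <- moto_to_fmr(
      propagate_moto(oto, ends0, oto_sd, max(n_draws, 1000)),
      calibration_curve(curve$C, curve$k), n_draws = n_draws)$sd^2
    v_end <- moto_to_fmr(
      propagate_moto(oto, ends, 0, max(n_draws, 1000)),
      calibration_curve(curve$C, curve$k), n_draws = n_draws)$sd^2
    m0 <- compute_moto(oto, ends)
    v_curve <- moto_to_fmr(m0, curve, moto_sd = 0, n_draws = n_draws)$sd^2
    tot <- v_oto + v_end + v_curve
    fr <- if (tot > 0) c(v_oto, v_end, v_curve) / tot else c(NA, NA, NA)
    c(fmr = full$mean, fmr_sd = full$sd, fr)
  }
  out <- t(mapply(one, d13C_oto, d13C_oto_sd))
  out <- as.data.frame(out)
  names(out) <- c("fmr", "fmr_sd", "frac_oto", "frac_endmembers", "frac_curve")
  out$d13C_oto <- d13C_oto
  out[, c("d13C_oto", "fmr", "fmr_sd",
          "frac_oto", "frac_endmembers", "frac_curve")]
}

#' Write / read a calibration curve as a plain-text key-value file
#'
#' The main file stores C, k, standard errors, sample size and seed; the
#' Monte Carlo ensemble, if present, is written alongside as
#' `<path>.ensemble.csv`.
#'
#' @param curve A `"calibration_curve"`.
#' @param path Output file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `"calibration_curve"`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  lines <- c(sprintf("C = %.17g", curve$C),
             sprintf("k = %.17g", curve$k),
             sprintf("se_C = %.17g", curve$se_C),
             sprintf("se_k = %.17g", curve$se_k),
             sprintf("n_fit = %d", curve$n_fit),
             sprintf("seed = %s", if (is.null(curve$seed)) "NA" else curve$seed))
  if (!is.null(curve$ensemble)) {
    ens_path <- paste0(path, ".ensemble.csv")
    utils::write.csv(as.data.frame(curve$ensemble), ens_path, row.names = FALSE)
    lines <- c(lines, sprintf("ensemble = %s", basename(ens_path)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    stop("calibration file not found: ", path)
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(key) kv$value[match(key, kv$key)]
  curve <- calibration_curve(C = as.numeric(get("C")),
                             k = as.numeric(get("k")),
                             se_C = as.numeric(get("se_C")),
                             se_k = as.numeric(get("se_k")))
  curve$n_fit <- as.integer(get("n_fit"))
  ens <- get("ensemble")
  if (!is.na(ens)) {
    ens_path <- file.path(dirname(path), ens)
    if (file.exists(ens_path))
      curve$ensemble <- as.matrix(utils::read.csv(ens_path))
    curve$ensemble_mean <- colMeans(curve$ensemble)
    curve$ensemble_sd <- apply(curve$ensemble, 2, stats::sd)
  }
  curve
}
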