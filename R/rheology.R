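# Aggregate per-frequency hydrodynamic-length fits into a rheological
# spectrum, compute the effective bending stiffness, and classify the
# scaling regime (frequency-independent wormlike chain vs the
# shear-coupled wormlike-bundle signature).

#' Power-law fit on log-log axes
#'
#' Ordinary least squares of log10(y) on log10(x): `y = prefactor *
#' x^exponent`.
#'
#' @param xs,ys Strictly positive numeric vectors (>= 3 points).
#' @return Object of class `power_law_fit`: `exponent`, `prefactor`,
#'   `standard_error` (of the exponent), `r_squared`, `n`.
#' @examples
#' fit_power_law(1:10, (1:10)^-0.25)
#' @export
fit_power_law <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys differ in length")
  if (length(xs) < 3) stop("need >= 3 points for a power-law fit")
  if (any(xs <= 0) || any(ys <= 0))
    stop("power-law fit requires strictly positive data")
  fit <- stats::lm(log10(ys) ~ log10(xs))
  sm <- suppressWarnings(summary(fit))   # exact power laws are legal input
  structure(list(
    exponent = unname(coef(fit)[2]),
    prefactor = 10^unname(coef(fit)[1]),
    standard_error = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    n = length(xs)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent %.4f +/- %.4f (r^2 = %.4f, n = %d)\n",
              x$exponent, x$standard_error, x$r_squared, x$n))
  invisible(x)
}

#' Assemble per-frequency fits into a rheological sweep
#'
#' Computes the effective bending stiffness \eqn{\kappa_{eff} =
#' l_\omega^4\,\omega} (units m^4/s, i.e. \eqn{\kappa/\zeta}) for every
#' record and, when a rod model supplies the drag coefficient, the
#' stiffness proper \eqn{\kappa = \zeta\,\kappa_{eff}} in J·m.  Duplicate
#' frequencies are collapsed (geometric mean of `l_omega`) with a
#' warning.
#'
#' @param fits List of `hydro_fit` objects (>= 3 distinct frequencies).
#' @param rod Optional [rod_model()] providing `zeta`.
#' @param bundle_label Free-text label (e.g. "thin", "thick").
#' @return Object of class `sweep_result` wrapping a data frame `records`
#'   with columns `frequency_hz`, `omega`, `l_omega`, `se_l_omega`,
#'   `kappa_eff`, (`kappa`,) `residual_norm`, `n_points`.
#' @export
build_sweep <- function(fits, rod = NULL, bundle_label = "") {
  if (inherits(fits, "hydro_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "hydro_fit")))
    stop("fits must be a list of hydro_fit objects")
  rec <- data.frame(
    frequency_hz = vapply(fits, `[[`, 0, "frequency_hz"),
    omega = vapply(fits, `[[`, 0, "omega"),
    l_omega = vapply(fits, `[[`, 0, "l_omega"),
    se_l_omega = vapply(fits, `[[`, 0, "se_l_omega"),
    residual_norm = vapply(fits, `[[`, 0, "residual_norm"),
    n_points = vapply(fits, `[[`, 0, "n_points"))
  if (anyDuplicated(rec$frequency_hz)) {
    warning("duplicate frequencies collapsed (geometric mean of l_omega)")
    rec <- do.call(rbind, lapply(split(rec, rec$frequency_hz), function(d) {
      d$l_omega[1] <- exp(mean(log(d$l_omega))); d[1, ]
    }))
    rec <- rec[order(rec$frequency_hz), ]
    rownames(rec) <- NULL
  }
  if (nrow(rec) < 3) stop("need >= 3 distinct frequencies for a sweep")
  rec$kappa_eff <- rec$l_omega^4 * rec$omega
  if (!is.null(rod)) rec$kappa <- rod$zeta * rec$kappa_eff
  structure(list(records = rec, bundle_label = bundle_label,
                 zeta = if (!is.null(rod)) rod$zeta else NA_real_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d frequencies%s\n", nrow(x$records),
              if (nzchar(x$bundle_label))
                paste0(" [", x$bundle_label, "]") else ""))
  print(x$records, digits = 4)
  invisible(x)
}

#' Classify the scaling regime of a frequency sweep
#'
#' Fits the power law of `l_omega` versus `omega`.  If the exponent is
#' compatible with -1/4 (within `tol` plus `se_factor` standard errors)
#' the bundle behaves as a wormlike chain with frequency-independent
#' stiffness (`WLC_constant`).  Otherwise the exponents of `kappa_eff`
#' versus `omega` and versus `l_omega` are reported; a
#' `kappa_eff`-vs-`l_omega` exponent compatible with +2 is the
#' shear-dominated wormlike-bundle signature (`WLB_shear_coupled`), and
#' anything else is labelled `free_power_law`.
#'
#' Sweeps with fewer than 4 frequencies or spanning less than a decade
#' are classified `"indeterminate"` (fewer than 4 always; a sub-decade
#' span adds a `low_power` flag rather than blocking classification).
#'
#' @param sweep A [build_sweep()] result.
#' @param tol Absolute exponent tolerance.
#' @param se_factor Multiplier on the fitted exponent standard error.
#' @return Object of class `scaling_model`: `model_kind` (one of
#'   `WLC_constant`, `WLB_shear_coupled`, `free_power_law`,
#'   `indeterminate`), `exponent_l_omega` (+ se), `exponent_kappa_omega`,
#'   `exponent_kappa_l` (kappa_eff vs l_omega), `flags`, and the
#'   underlying `power_law_fit`s.
#' @export
classify_regime <- function(sweep, tol = 0.05, se_factor = 2) {
  stopifnot(inherits(sweep, "sweep_result"))
  rec <- sweep$records
  flags <- character(0)
  if (nrow(rec) < 4)
    return(structure(list(model_kind = "indeterminate",
                          flags = "too_few_frequencies"),
                     class = "scaling_model"))
  span_dec <- log10(max(rec$omega) / min(rec$omega))
  if (span_dec < 1) flags <- c(flags, "low_power")

  pl_l <- fit_power_law(rec$omega, rec$l_omega)
  pl_ko <- fit_power_law(rec$omega, rec$kappa_eff)
  pl_kl <- fit_power_law(rec$l_omega, rec$kappa_eff)

  band_l <- tol + se_factor * pl_l$standard_error
  band_kl <- tol + se_factor * pl_kl$standard_error
  kind <- if (abs(pl_l$exponent + 0.25) <= band_l) {
    "WLC_constant"
  } else if (abs(pl_kl$exponent - 2) <= band_kl) {
    "WLB_shear_coupled"
  } else {
    "free_power_law"
  }
  structure(list(
    model_kind = kind,
    exponent_l_omega = pl_l$exponent,
    se_l_omega_exponent = pl_l$standard_error,
    exponent_kappa_omega = pl_ko$exponent,
    exponent_kappa_l = pl_kl$exponent,
    fits = list(l_omega_vs_omega = pl_l, kappa_vs_omega = pl_ko,
                kappa_vs_l_omega = pl_kl),
    tol = tol, se_factor = se_factor, flags = flags
  ), class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("<scaling_model> %s", x$model_kind))
  if (!is.null(x$exponent_l_omega))
    cat(sprintf(" (l_omega ~ omega^%.3f, kappa_eff ~ omega^%.3f, ~ l_omega^%.3f)",
                x$exponent_l_omega, x$exponent_kappa_omega, x$exponent_kappa_l))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Long-time stability (drift) test of the hydrodynamic length
#'
#' A fixed-frequency recording held for a long time should show no trend
#' in the measured hydrodynamic length.  Regresses `l_omega` on time and
#' reports the slope, its standard error, and the p-value of the
#' zero-slope hypothesis, plus the relative drift over the observation
#' window.
#'
#' @param times Observation times in s.
#' @param l_omegas Hydrodynamic lengths in m.
#' @return List: `slope` (m/s), `se`, `p_value`, `relative_drift`
#'   (fractional change over the window), `n`.
#' @export
drift_test <- function(times, l_omegas) {
  if (length(times) != length(l_omegas) || length(times) < 3)
    stop("need >= 3 paired observations")
  fit <- stats::lm(l_omegas ~ times)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm[2, 1]
  list(slope = slope, se = sm[2, 2], p_value = sm[2, 4],
       relative_drift = slope * diff(range(times)) / mean(l_omegas),
       n = length(times))
}
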