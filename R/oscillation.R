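# Isolate the drive-frequency oscillation from a kymograph and fit the
# hydrodynamic length from its spatial decay.
#
# The band pass is a discrete Fourier projection at exactly the drive
# frequency over a whole number of periods (first and last recorded
# periods excluded): with the drive frequency known there is no reason to
# design a filter with a passband, and projection over integer periods is
# exact for noiseless sinusoids and orthogonal to DC and to harmonics.

#' Complex oscillation amplitude per position at the drive frequency
#'
#' For every x position of a kymograph, projects y(t) onto
#' \eqn{e^{-i\omega t}} over an integer number of drive periods, after
#' excluding the first and last recorded periods (transients and filter
#' border effects).  Returns amplitude and phase per position.
#'
#' Columns are used only if at least 90% of their frames in the analysis
#' window are valid; missing samples are filled by linear interpolation.
#'
#' @param kymo A [kymograph()].
#' @param drive_hz Drive frequency in Hz; defaults to the kymograph's
#'   drive metadata.
#' @param exclude_periods Whole periods dropped at each end of the
#'   recording.
#' @param min_valid_fraction Minimum fraction of valid frames per column.
#' @return Object of class `amplitude_profile`: list with `x`,
#'   `amplitude` (m), `phase` ((-pi, pi]), `cvalue` (complex amplitude),
#'   `n_periods_used`, `omega`, and `drive_point` when known.
#' @export
bandpass <- function(kymo, drive_hz = NULL, exclude_periods = 1L,
                     min_valid_fraction = 0.9) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(drive_hz)) {
    if (is.null(kymo$drive)) stop("drive_hz not given and no drive metadata")
    drive_hz <- kymo$drive$frequency_hz
  }
  omega <- 2 * pi * drive_hz
  dt <- stats::median(diff(kymo$times))
  spp <- 1 / (drive_hz * dt)
  if (spp < 3)
    stop(sprintf("drive at %.3g Hz not resolvable at %.3g s frame interval",
                 drive_hz, dt))
  m <- as.integer(round(spp))
  if (abs(spp - m) > 0.01 * m)
    stop("frame interval is not commensurate with the drive period")
  nt <- nrow(kymo$y)
  n_per <- nt %/% m
  use_per <- n_per - 2L * exclude_periods
  if (use_per < 3L)
    stop(sprintf(
      "only %d whole periods recorded; need >= %d after excluding %d at each end",
      n_per, 3L + 2L * exclude_periods, exclude_periods))
  win <- seq.int(exclude_periods * m + 1L, (exclude_periods + use_per) * m)

  tt <- kymo$times[win]
  # for y(t) = Re[Y e^{-i omega t}], 2 <y e^{+i omega t}> recovers Y
  basis <- exp(1i * omega * tt)
  nc <- ncol(kymo$y)
  cval <- rep(NA_complex_, nc)
  usable <- rep(FALSE, nc)
  for (j in seq_len(nc)) {
    if (j %in% kymo$excluded_cols) next
    yj <- kymo$y[win, j]
    okf <- is.finite(yj)
    if (mean(okf) < min_valid_fraction || sum(okf) < 4) next
    if (!all(okf))
      yj <- stats::approx(tt[okf], yj[okf], xout = tt, rule = 2)$y
    cval[j] <- 2 * mean(yj * basis)
    usable[j] <- TRUE
  }
  keep <- which(usable)
  structure(list(
    x = kymo$x[keep], amplitude = Mod(cval[keep]), phase = Arg(cval[keep]),
    cvalue = cval[keep], n_periods_used = use_per, omega = omega,
    frequency_hz = drive_hz,
    drive_point = if (!is.null(kymo$drive)) kymo$drive$drive_point else NULL
  ), class = "amplitude_profile")
}

#' @export
print.amplitude_profile <- function(x, ...) {
  cat(sprintf(
    "<amplitude_profile> %d positions at %.3g Hz (%d periods used)\n",
    length(x$x), x$omega / (2 * pi), x$n_periods_used))
  invisible(x)
}

# model profile: complex amplitude at positions x for parameters
# (l_omega, y0, x0, phi); positions before the drive point are clamped to
# eta = 0 (they are excluded from fitting windows in practice)
profile_model <- function(x, l_omega, y0, x0, phi, drive_point) {
  eta <- pmax(x - x0, 0) / l_omega
  steady_amplitude(eta, y0, drive_point) * exp(1i * phi)
}

#' Fit the hydrodynamic length to an amplitude profile
#'
#' Least-squares fit of the analytic driven-rod profile to the measured
#' complex amplitude versus position.  Free parameters: the hydrodynamic
#' length `l_omega`, the drive amplitude `y0`, an x-origin offset `x0`
#' (the effective drive point sits inside the bead-excluded region), and
#' a global phase.  In `mode = "envelope"` only the amplitude envelope is
#' fit (3 parameters, no phase).
#'
#' @param profile An [bandpass()] `amplitude_profile`.
#' @param drive_point `"end"` or `"middle"`; defaults to profile
#'   metadata.
#' @param mode `"complex"` (default; the two-wave interference is
#'   phase-sensitive) or `"envelope"`.
#' @param l0 Optional initial guess for `l_omega` in m; by default the
#'   distance over which the measured amplitude first falls by
#'   \eqn{e^{-\tilde S}}.
#' @return Object of class `hydro_fit`: `l_omega`, `y0_fit`, `x0`,
#'   `phase`, `omega`, `frequency_hz`, `drive_point`, `mode`,
#'   `residual_norm` (m), `covariance` (parameter covariance, same order
#'   as `par_names`), `se_l_omega`, `n_points`, `flags`.
#' @export
fit_hydrodynamic_length <- function(profile, drive_point = NULL,
                                    mode = c("complex", "envelope"),
                                    l0 = NULL) {
  stopifnot(inherits(profile, "amplitude_profile"))
  mode <- match.arg(mode)
  if (is.null(drive_point)) drive_point <- profile$drive_point %||% "end"
  x <- profile$x; cv <- profile$cvalue
  ok <- is.finite(x) & is.finite(Re(cv))
  x <- x[ok]; cv <- cv[ok]
  n <- length(x)
  if (n < 8) stop("need >= 8 valid positions to fit l_omega")
  amp <- Mod(cv)
  if (max(amp) <= 0 || stats::sd(amp) / max(amp) < 1e-3)
    stop("degenerate flat amplitude profile; nothing to fit")

  dc <- decay_constants()
  S_t <- dc$S_tilde
  C_t <- dc$C_tilde
  # Initial guesses from the leading decaying wave, for which
  # ln|Y| ~ -S~ (x - x0)/l  and  arg Y ~ phi + C~ (x - x0)/l are linear
  # in x.  Use the early part of the profile (above 20% of the peak).
  first_drop <- which(amp <= 0.2 * max(amp))[1]
  early <- seq_len(if (is.na(first_drop)) length(amp) else first_drop - 1L)
  l_est <- c()
  sl_a <- NA_real_
  if (length(early) >= 3) {
    fa <- stats::lm(log(amp[early]) ~ x[early])
    sl_a <- unname(coef(fa)[2])
    if (is.finite(sl_a) && sl_a < 0) l_est <- c(l_est, -S_t / sl_a)
    ph <- Arg(cv[early])
    dph <- diff(ph)
    dph <- dph - 2 * pi * round(dph / (2 * pi))    # unwrap
    ph_u <- cumsum(c(ph[1], dph))
    fp <- stats::lm(ph_u ~ x[early])
    sl_p <- unname(coef(fp)[2])
    if (is.finite(sl_p) && sl_p > 0) l_est <- c(l_est, C_t / sl_p)
  }
  if (is.null(l0)) {
    l0 <- if (length(l_est)) exp(mean(log(l_est))) else diff(range(x)) / 4
  }
  x0_init <- x[1] - 0.25 * l0
  y0_init <- 2 * amp[1] * exp(S_t * 0.25)
  phi_init <- Arg(cv[1] * exp(-1i * C_t * 0.25))

  make_resid <- if (mode == "complex") {
    function(p) {
      m <- profile_model(x, exp(p[1]), exp(p[2]), p[3], p[4], drive_point)
      c(Re(m - cv), Im(m - cv))
    }
  } else {
    function(p) {
      m <- profile_model(x, exp(p[1]), exp(p[2]), p[3], 0, drive_point)
      Mod(m) - amp
    }
  }
  resid_fn <- make_resid
  best <- NULL
  for (lf in c(1, 0.6, 1.6)) {
    par0 <- c(log_l = log(l0 * lf), log_y0 = log(y0_init), x0 = x0_init)
    if (mode == "complex") par0 <- c(par0, phi = phi_init)
    f <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(f) || f$info %in% c(0, 9)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    stop(sprintf(
      "l_omega fit did not converge from any start (l0 = %.3g m, bounds [%.3g, %.3g] m)",
      l0, 0.6 * l0, 1.6 * l0))
  fit <- best
  p <- fit$par
  l_omega <- exp(p[[1]]); y0_fit <- exp(p[[2]]); x0 <- p[[3]]
  phase <- if (mode == "complex") p[[4]] else NA_real_

  rv <- resid_fn(p)
  dof <- max(length(rv) - length(p), 1)
  s2 <- sum(rv^2) / dof
  # covariance in the original parameterization via the delta method
  J <- jac_num(resid_fn, p)
  scale <- c(l_omega, y0_fit, rep(1, length(p) - 2))
  cov_log <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, length(p), length(p))
  })
  covariance <- cov_log * tcrossprod(scale)
  se_l <- sqrt(covariance[1, 1])

  flags <- character(0)
  span <- diff(range(x))
  if (span < 2 * l_omega) flags <- c(flags, "short_span")
  if (is.finite(se_l) && se_l > 0.5 * l_omega)
    flags <- c(flags, "wide_uncertainty")

  structure(list(
    l_omega = l_omega, y0_fit = y0_fit, x0 = x0, phase = phase,
    omega = profile$omega, frequency_hz = profile$frequency_hz,
    drive_point = drive_point, mode = mode,
    residual_norm = sqrt(mean(rv^2)), covariance = covariance,
    par_names = names(par0), se_l_omega = se_l, n_points = n,
    flags = flags
  ), class = "hydro_fit")
}

# forward-difference Jacobian, adequate for error bars
jac_num <- function(fn, p, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (i in seq_along(p)) {
    h <- eps * max(abs(p[i]), 1)
    pi_ <- p; pi_[i] <- pi_[i] + h
    J[, i] <- (fn(pi_) - f0) / h
  }
  J
}

#' @export
print.hydro_fit <- function(x, ...) {
  cat(sprintf(
    "<hydro_fit> l_omega = %.4g m (se %.2g) at %.3g Hz [%s, %s-driven]%s\n",
    x$l_omega, x$se_l_omega, x$frequency_hz, x$mode, x$drive_point,
    if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ","))
    else ""))
  invisible(x)
}
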