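# Physical model of a driven semiflexible bundle at low Reynolds number:
# transverse drag balances bending, zeta * (y_t - u) = -kappa * y_xxxx.

#' Boltzmann constant
#'
#' CODATA value of kB in J/K, used to convert between bending stiffness
#' and persistence length (kappa = kB * T * lp).
#' @export
kB <- 1.380649e-23

#' Physical description of a bundle as a homogeneous elastic rod
#'
#' Collects the parameters of the overdamped bending equation
#' \eqn{\zeta (y_t - u) = -\kappa\, y_{xxxx}}: bending stiffness,
#' geometry, and the transverse slender-body drag per unit length derived
#' from the medium viscosity via [drag_coefficient()].
#'
#' Exactly one of `kappa` and `persistence_length` must be supplied; the
#' other is derived through \eqn{\kappa = k_B T\, l_p}.
#'
#' @param kappa Bending stiffness in J·m.
#' @param persistence_length Persistence length in m.
#' @param contour_length Contour length L in m.
#' @param diameter Bundle diameter d in m (must satisfy L > d).
#' @param medium_viscosity Dynamic viscosity of the medium in Pa·s.
#' @param temperature Temperature in K.
#' @param background_velocity Transverse background flow u in m/s.  The
#'   drive moves the trapped bead, not the fluid, so the default is 0.
#' @return An object of class `rod_model`: a list with fields `kappa`,
#'   `persistence_length`, `contour_length`, `diameter`,
#'   `medium_viscosity`, `temperature`, `zeta` (drag per unit length,
#'   Pa·s) and `background_velocity`.
#' @examples
#' rod <- rod_model(kappa = 6e-24, contour_length = 20e-6, diameter = 60e-9,
#'                  medium_viscosity = 0.05)
#' rod$zeta
#' @export
rod_model <- function(kappa = NULL, persistence_length = NULL,
                      contour_length, diameter, medium_viscosity,
                      temperature = 296, background_velocity = 0) {
  if (is.null(kappa) == is.null(persistence_length))
    stop("supply exactly one of `kappa` and `persistence_length`")
  if (temperature <= 0) stop("temperature must be positive")
  if (is.null(kappa)) kappa <- kB * temperature * persistence_length
  if (is.null(persistence_length)) persistence_length <- kappa / (kB * temperature)
  if (kappa <= 0) stop("kappa must be positive")
  if (contour_length <= 0 || diameter <= 0)
    stop("contour_length and diameter must be positive")
  if (contour_length <= diameter)
    stop("slender-rod model requires contour_length > diameter")
  zeta <- drag_coefficient(medium_viscosity, contour_length, diameter)
  structure(list(
    kappa = kappa,
    persistence_length = persistence_length,
    contour_length = contour_length,
    diameter = diameter,
    medium_viscosity = medium_viscosity,
    temperature = temperature,
    zeta = zeta,
    background_velocity = background_velocity
  ), class = "rod_model")
}

#' @export
print.rod_model <- function(x, ...) {
  cat("<rod_model>\n")
  cat(sprintf("  kappa      %.4g J·m   (lp = %.4g m)\n",
              x$kappa, x$persistence_length))
  cat(sprintf("  L          %.4g m,  d = %.4g m  (L/d = %.3g)\n",
              x$contour_length, x$diameter, x$contour_length / x$diameter))
  cat(sprintf("  viscosity  %.4g Pa·s  ->  zeta = %.4g Pa·s\n",
              x$medium_viscosity, x$zeta))
  cat(sprintf("  kappa/zeta %.4g m^4/s\n", x$kappa / x$zeta))
  invisible(x)
}

#' Sinusoidal drive protocol for a trapped-bead excitation
#'
#' Defines the oscillation imposed on the bundle by the optical trap: a
#' transverse sinusoid of amplitude `amplitude` at `frequency_hz`, applied
#' at one end or at the middle of the contour.  Formulas use the angular
#' frequency `omega = 2*pi*frequency_hz`; metadata keeps Hz.
#'
#' When `frame_interval` is `NULL` an acquisition interval is chosen that
#' is commensurate with the period (an integer number of frames per
#' period, at most 20, camera-limited below by `min_interval`), so that
#' Fourier projection over whole periods is exact.
#'
#' @param amplitude Drive amplitude y0 in m.
#' @param frequency_hz Drive frequency in cycles/s (the protocol spans
#'   0.04–2.5 Hz in typical experiments).
#' @param drive_point `"end"` or `"middle"`.
#' @param n_periods Number of full periods recorded (>= 3; >= 5 if the
#'   first and last periods are to be discarded while keeping 3 for the
#'   band-pass, the default analysis).
#' @param frame_interval Time between frame starts in s, or `NULL` to
#'   choose a period-commensurate interval.
#' @param exposure Camera exposure in s (defaults to 50 ms, a typical
#'   minimum for dim fluorescent bundles).
#' @param min_interval Smallest realizable frame interval in s.
#' @return Object of class `drive_protocol` with fields `amplitude`,
#'   `frequency_hz`, `omega`, `drive_point`, `n_periods`,
#'   `frame_interval`, `exposure`, `frames_per_period`, `n_frames`.
#' @export
drive_protocol <- function(amplitude, frequency_hz,
                           drive_point = c("end", "middle"),
                           n_periods = 5, frame_interval = NULL,
                           exposure = 0.05, min_interval = 0.06) {
  drive_point <- match.arg(drive_point)
  if (amplitude <= 0) stop("amplitude must be positive")
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  if (n_periods < 3) stop("need at least 3 periods to assess a steady state")
  period <- 1 / frequency_hz
  if (is.null(frame_interval)) {
    fpp <- min(20, round(period / min_interval), floor(period / exposure))
    fpp <- max(fpp, 4)
    frame_interval <- period / fpp
  } else {
    fpp <- period / frame_interval
  }
  if (frame_interval < exposure)
    stop("frame_interval shorter than the exposure time")
  structure(list(
    amplitude = amplitude,
    frequency_hz = frequency_hz,
    omega = 2 * pi * frequency_hz,
    drive_point = drive_point,
    n_periods = n_periods,
    frame_interval = frame_interval,
    exposure = exposure,
    frames_per_period = fpp,
    n_frames = floor(n_periods * period / frame_interval + 1e-9)
  ), class = "drive_protocol")
}

#' @export
print.drive_protocol <- function(x, ...) {
  cat(sprintf("<drive_protocol> y0 = %.3g m at %.3g Hz (%s-driven)\n",
              x$amplitude, x$frequency_hz, x$drive_point))
  cat(sprintf("  %d periods, %d frames (interval %.3g s, exposure %.3g s)\n",
              x$n_periods, x$n_frames, x$frame_interval, x$exposure))
  invisible(x)
}

#' Spatial decay constants of the driven-beam solution
#'
#' Substituting the traveling-wave ansatz \eqn{y \propto e^{ik\eta - i\omega t}}
#' into the overdamped bending equation and nondimensionalizing lengths by
#' the hydrodynamic length turns the equation of motion into the quartic
#' dispersion relation \eqn{k^4 = i}.  Its first-quadrant root
#' \eqn{k = \tilde C + i\tilde S} supplies the spatial oscillation constant
#' \eqn{\tilde C} and decay constant \eqn{\tilde S} of the excitation wave
#' (the roles swap for the reflected wave).
#'
#' The root is located numerically with a polynomial root finder; it equals
#' \eqn{e^{i\pi/8}}, so \eqn{\tilde C^2 + \tilde S^2 = 1}.
#'
#' @return Object of class `decay_constants`: list with `C_tilde`
#'   (~0.92) and `S_tilde` (~0.38).
#' @examples
#' dc <- decay_constants()
#' round(c(dc$C_tilde, dc$S_tilde), 2)
#' @export
decay_constants <- function() {
  roots <- polyroot(c(complex(real = 0, imaginary = -1), 0, 0, 0, 1))
  k <- roots[Re(roots) > 0 & Im(roots) > 0]
  stopifnot(length(k) == 1L)
  structure(list(C_tilde = Re(k), S_tilde = Im(k)), class = "decay_constants")
}

#' @export
print.decay_constants <- function(x, ...) {
  cat(sprintf("<decay_constants> C~ = %.7f, S~ = %.7f (k^4 = i)\n",
              x$C_tilde, x$S_tilde))
  invisible(x)
}

#' Transverse slender-body drag coefficient per unit length
#'
#' Low-Reynolds-number drag per unit length of a rigid rod moving
#' perpendicular to its axis,
#' \eqn{\zeta = 4\pi\eta / (\ln(L/d) + 0.84)}.
#' The logarithmic geometry dependence means thickness changes of a
#' bundle perturb the drag only weakly when L >> d.
#'
#' @param viscosity Dynamic viscosity in Pa·s.
#' @param L Rod length in m.
#' @param d Rod diameter in m; requires L > d.
#' @return Drag coefficient in Pa·s (force per unit length per velocity).
#' @examples
#' drag_coefficient(1e-3, 20e-6, 20e-9)
#' @export
drag_coefficient <- function(viscosity, L, d) {
  if (viscosity <= 0) stop("viscosity must be positive")
  if (d <= 0 || L <= d) stop("need L > d > 0 for a slender rod")
  4 * pi * viscosity / (log(L / d) + 0.84)
}

#' Hydrodynamic length of a driven filament
#'
#' The length scale \eqn{l_\omega = (\kappa / (\zeta \omega))^{1/4}} over
#' which the amplitude of a transverse oscillation imposed at one point
#' decays along the filament.  Equivalently
#' \eqn{(k_B T l_p / (\omega \zeta))^{1/4}} with \eqn{l_p = \kappa/k_B T}.
#'
#' @param kappa Bending stiffness in J·m.
#' @param zeta Transverse drag per unit length in Pa·s.
#' @param omega Angular drive frequency in rad/s.
#' @return Hydrodynamic length in m (vectorized over any argument).
#' @seealso [effective_stiffness()] for the inverse map.
#' @export
hydrodynamic_length <- function(kappa, zeta, omega) {
  if (any(kappa <= 0) || any(zeta <= 0) || any(omega <= 0))
    stop("kappa, zeta and omega must all be positive")
  (kappa / (zeta * omega))^0.25
}

#' Effective bending stiffness from a measured decay length
#'
#' Inverts the definition of the hydrodynamic length:
#' \eqn{\kappa_{eff} = \kappa/\zeta = l_\omega^4\,\omega} in m^4/s.  When
#' the drag coefficient is known, the bending stiffness proper,
#' \eqn{\kappa = \zeta\, l_\omega^4\, \omega} in J·m, is also returned.
#'
#' @param l_omega Hydrodynamic length in m.
#' @param omega Angular frequency in rad/s.
#' @param zeta Optional drag coefficient in Pa·s.
#' @return List with `kappa_eff` (m^4/s) and, when `zeta` is given,
#'   `kappa` (J·m).
#' @export
effective_stiffness <- function(l_omega, omega, zeta = NULL) {
  if (any(l_omega <= 0) || any(omega <= 0))
    stop("l_omega and omega must be positive")
  out <- list(kappa_eff = l_omega^4 * omega)
  if (!is.null(zeta)) out$kappa <- zeta * out$kappa_eff
  out
}

# Complex wave numbers of the two decaying partial waves: the excitation
# wave k1 = C + iS and its medium-reflected counterpart k2 = i*k1.
wave_numbers <- function(dc = decay_constants()) {
  k1 <- complex(real = dc$C_tilde, imaginary = dc$S_tilde)
  c(k1, 1i * k1)
}

#' Complex steady-state amplitude profile of a driven rod
#'
#' The steady oscillation is \eqn{y(\eta, t) = \mathrm{Re}[Y(\eta)
#' e^{-i\omega t}]} with \eqn{\eta = x / l_\omega}.  For an end-driven rod
#' \eqn{Y(\eta) = (y_0/2)(e^{ik_1\eta} + e^{ik_2\eta})} with
#' \eqn{k_1 = \tilde C + i\tilde S}, \eqn{k_2 = i k_1}; for a rod driven
#' at its middle the weights become \eqn{(1-i)} and \eqn{(1+i)}
#' respectively, on each arm of the contour.
#'
#' @param eta Dimensionless position x / l_omega, >= 0.
#' @param y0 Drive amplitude in m.
#' @param drive_point `"end"` or `"middle"`.
#' @return Complex vector Y(eta) in m.
#' @export
steady_amplitude <- function(eta, y0, drive_point = c("end", "middle")) {
  drive_point <- match.arg(drive_point)
  if (any(eta < 0)) stop("eta must be non-negative (one side of the contour)")
  k <- wave_numbers()
  w <- if (drive_point == "end") c(1, 1) else c(1 - 1i, 1 + 1i)
  (y0 / 2) * (w[1] * exp(1i * k[1] * eta) + w[2] * exp(1i * k[2] * eta))
}

#' Transverse displacement of a rod driven sinusoidally at one end
#'
#' Evaluates the closed-form steady solution
#' \deqn{y(\eta,t) = \frac{y_0}{2}\left[e^{-\tilde S\eta}
#'   \cos(\tilde C\eta - \omega t) + e^{-\tilde C\eta}
#'   \cos(\tilde S\eta + \omega t)\right],}
#' a superposition of an excitation wave and its reflection by the
#' medium, each decaying on the scale of the hydrodynamic length
#' (\eqn{\eta = x/l_\omega}).  At \eqn{\eta = 0} the displacement is the
#' imposed \eqn{y_0 \cos\omega t}.
#'
#' @param eta Dimensionless position(s) x / l_omega, >= 0.
#' @param t Time(s) in s.  `eta` and `t` are recycled elementwise.
#' @param y0 Drive amplitude in m.
#' @param omega Angular frequency in rad/s.
#' @return Displacement in m.
#' @export
end_driven_solution <- function(eta, t, y0, omega) {
  Re(steady_amplitude(eta, y0, "end") * exp(-1i * omega * t))
}

#' Transverse displacement of a rod driven sinusoidally at its middle
#'
#' One arm (\eqn{\eta \ge 0}) of the symmetric middle-driven solution
#' \deqn{y(\eta,t) = \frac{y_0}{2}\left\{e^{-\tilde S\eta}
#'   [\cos(\tilde C\eta-\omega t)+\sin(\tilde C\eta-\omega t)] +
#'   e^{-\tilde C\eta}[\cos(\tilde S\eta+\omega t)+
#'   \sin(\tilde S\eta+\omega t)]\right\}.}
#' Both arms carry identical profiles.
#'
#' @inheritParams end_driven_solution
#' @return Displacement in m.
#' @export
middle_driven_solution <- function(eta, t, y0, omega) {
  Re(steady_amplitude(eta, y0, "middle") * exp(-1i * omega * t))
}
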