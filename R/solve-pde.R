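# Finite-difference reference solver for the overdamped bending equation
#   zeta * (y_t - u) = -kappa * y_xxxx
# with a clamped-displacement, torque-free sinusoidal drive at x = 0 and a
# free far end (y_xx = y_xxx = 0) at x = L.  Crank-Nicolson in time,
# second-order central stencils in space; ghost nodes eliminate the
# boundary conditions.  The scheme is unconditionally stable, so grid
# requirements are accuracy requirements, validated up front.

#' Finite-difference solution of the driven overdamped bending equation
#'
#' Integrates \eqn{\zeta (y_t - u) = -\kappa\, y_{xxxx}} on
#' \eqn{x \in [0, L]} with the drive \eqn{y(0,t) = y_0\cos\omega t}
#' applied as a clamped displacement with zero curvature (torque-free
#' pivot) at the driven end, and a force- and torque-free far end.
#' Serves as an independent numerical ground truth for the closed-form
#' steady solutions.
#'
#' Starting from a straight rod, the solution approaches the analytic
#' steady state; the first `n_transient_periods` periods are marked as
#' transient and excluded from steady-state comparisons.
#'
#' @param rod A [rod_model()].
#' @param drive A [drive_protocol()] (only end drive is supported by the
#'   solver; the middle-driven problem is its mirror image on each arm).
#' @param nodes_per_lomega Spatial resolution: grid nodes per
#'   hydrodynamic length (>= 10).
#' @param steps_per_period Temporal resolution: time steps per drive
#'   period (>= 20).
#' @param n_transient_periods Whole periods discarded as transient
#'   (>= 1).
#' @return List of class `pde_solution`: `y` (time x space matrix, m),
#'   `x` (m), `times` (s), `l_omega` (m), `steady` (logical index of
#'   post-transient times), `dx`, `dt`.
#' @seealso [end_driven_solution()] for the closed form it converges to.
#' @export
solve_pde <- function(rod, drive, nodes_per_lomega = 15,
                      steps_per_period = 120, n_transient_periods = 1) {
  stopifnot(inherits(rod, "rod_model"), inherits(drive, "drive_protocol"))
  if (drive$drive_point != "end")
    stop("solve_pde integrates the end-driven problem; a middle-driven rod ",
         "is two mirrored end-driven arms")
  if (nodes_per_lomega < 10 || steps_per_period < 20)
    stop(sprintf(
      "grid too coarse: %d nodes per l_omega (need >= 10), %d steps per period (need >= 20)",
      nodes_per_lomega, steps_per_period))

  omega <- drive$omega
  D <- rod$kappa / rod$zeta
  l_omega <- hydrodynamic_length(rod$kappa, rod$zeta, omega)
  L <- rod$contour_length
  period <- 2 * pi / omega

  dx <- l_omega / nodes_per_lomega
  N <- max(8L, ceiling(L / dx))          # unknown nodes 1..N; node 0 driven
  dx <- L / N
  dt <- period / steps_per_period
  n_periods_total <- drive$n_periods
  nt <- n_periods_total * steps_per_period

  # Fourth-derivative operator on unknowns y_1..y_N with ghost-eliminated
  # boundary rows (see file header).
  A <- Matrix::bandSparse(N, N, k = -2:2, diagonals = list(
    rep(1, N - 2), rep(-4, N - 1), rep(6, N), rep(-4, N - 1), rep(1, N - 2)))
  A <- as(A, "generalMatrix")
  A[1, 1:3] <- c(5, -4, 1)
  A[N - 1, (N - 3):N] <- c(1, -4, 5, -2)
  A[N, (N - 2):N] <- c(2, -4, 2)
  # boundary forcing: rows 1 and 2 reference the prescribed node 0
  bvec <- numeric(N); bvec[1] <- -2; bvec[2] <- 1

  r <- D * dt / dx^4
  I_N <- Matrix::Diagonal(N)
  M_lhs <- I_N + (r / 2) * A
  M_rhs <- I_N - (r / 2) * A
  lhs_lu <- Matrix::lu(M_lhs)

  # sine start: drive and straight-rod initial condition are continuous at
  # t = 0, so no step-like pulse feeds the slowly relaxing long-wavelength
  # modes (their hyperdiffusive decay rate ~ D (pi/L)^4 is far below omega)
  y0_of <- function(t) drive$amplitude * sin(omega * t)
  u <- rod$background_velocity

  times <- seq(0, by = dt, length.out = nt + 1)
  Y <- matrix(0, nrow = nt + 1, ncol = N + 1)
  y <- numeric(N)
  for (n in seq_len(nt)) {
    t0 <- times[n]; t1 <- times[n + 1]
    rhs <- as.numeric(M_rhs %*% y) -
      (r / 2) * (y0_of(t0) + y0_of(t1)) * bvec + dt * u
    y <- as.numeric(Matrix::solve(lhs_lu, rhs))
    Y[n + 1, ] <- c(y0_of(t1), y)
  }

  steady <- times >= n_transient_periods * period - 1e-12
  structure(list(
    y = Y, x = seq(0, L, by = dx), times = times, l_omega = l_omega,
    steady = steady, dx = dx, dt = dt, rod = rod, drive = drive
  ), class = "pde_solution")
}

#' Steady-state L2 discrepancy between the solver and the closed form
#'
#' Relative L2 error (normalized by the drive amplitude) between a
#' [solve_pde()] field and the end-driven analytic solution, over the
#' post-transient time window.
#'
#' @param sol A `pde_solution`.
#' @return Scalar relative L2 error (dimensionless, in units of y0).
#' @export
pde_l2_error <- function(sol) {
  stopifnot(inherits(sol, "pde_solution"))
  eta <- sol$x / sol$l_omega
  tt <- sol$times[sol$steady]
  # solver drives with sin(omega t) = cos(omega (t - T/4)); shift the
  # cosine-referenced closed form accordingly
  tshift <- pi / (2 * sol$drive$omega)
  ref <- outer(tt, eta, function(t, e)
    end_driven_solution(e, t - tshift, sol$drive$amplitude, sol$drive$omega))
  num <- sol$y[sol$steady, , drop = FALSE]
  sqrt(mean((num - ref)^2)) / sol$drive$amplitude
}
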