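# Closed-form physics: dispersion-relation constants, drag, hydrodynamic
# length, and the driven-rod solutions.

test_that("dispersion-relation root matches the closed form e^{i pi/8}", {
  dc <- decay_constants()
  # independent oracle: k^4 = i has the first-quadrant root exp(i*pi/8)
  expect_equal(dc$C_tilde, cos(pi / 8), tolerance = 1e-12)
  expect_equal(dc$S_tilde, sin(pi / 8), tolerance = 1e-12)
  expect_equal(dc$C_tilde^2 + dc$S_tilde^2, 1, tolerance = 1e-12)
  expect_true(dc$C_tilde > dc$S_tilde && dc$S_tilde > 0)
  expect_identical(round(c(dc$C_tilde, dc$S_tilde), 2), c(0.92, 0.38))
})

test_that("slender-body drag is linear in viscosity, increasing in d, and
          matches direct evaluation", {
  z <- drag_coefficient(1e-3, 20e-6, 20e-9)
  expect_equal(drag_coefficient(2e-3, 20e-6, 20e-9), 2 * z)
  expect_gt(drag_coefficient(1e-3, 20e-6, 40e-9), z)
  # frozen direct evaluation of 4*pi*eta/(ln(L/d) + 0.84)
  expect_equal(z, 1.62193696e-3, tolerance = 1e-7)
  expect_error(drag_coefficient(0, 1, 0.1), "positive")
  expect_error(drag_coefficient(1e-3, 1e-6, 2e-6), "L > d")
})

test_that("hydrodynamic length obeys its quarter-power scaling", {
  expect_equal(hydrodynamic_length(1, 1, 1), 1)
  expect_equal(hydrodynamic_length(1e-24, 0.1, 16 * 2) /
                 hydrodynamic_length(1e-24, 0.1, 2), 1 / 2)
  set.seed(4)
  for (i in 1:20) {
    k <- 10^runif(1, -26, -20); z <- 10^runif(1, -3, 1)
    w <- 10^runif(1, -2, 2)
    expect_equal(hydrodynamic_length(k, z, 2 * w) /
                   hydrodynamic_length(k, z, w), 2^-0.25,
                 tolerance = 1e-12)
  }
  expect_error(hydrodynamic_length(1, 1, -1), "positive")
})

test_that("effective stiffness inverts the hydrodynamic length exactly", {
  expect_equal(effective_stiffness(1, 1)$kappa_eff, 1)
  expect_equal(effective_stiffness(2, 3)$kappa_eff /
                 effective_stiffness(1, 3)$kappa_eff, 16)
  set.seed(5)
  for (i in 1:20) {
    keff <- 10^runif(1, -24, -20); w <- 10^runif(1, -1, 2)
    l <- hydrodynamic_length(keff, 1, w)
    expect_equal(effective_stiffness(l, w)$kappa_eff, keff,
                 tolerance = 1e-12)
  }
  es <- effective_stiffness(2e-6, 3, zeta = 0.1)
  expect_equal(es$kappa, 0.1 * es$kappa_eff)
})

test_that("end-driven solution meets its boundary condition, decays, and
          equals term-by-term evaluation", {
  y0 <- 1e-6; om <- 2.7
  tt <- seq(0, 3, by = 0.17)
  expect_equal(end_driven_solution(0, tt, y0, om), y0 * cos(om * tt),
               tolerance = 1e-12)
  expect_lt(abs(end_driven_solution(80, 0.3, y0, om)), 1e-12 * y0)
  # independent term-by-term evaluation of the printed two-wave formula
  C <- cos(pi / 8); S <- sin(pi / 8)
  eta <- seq(0, 8, by = 0.31)
  for (t in c(0, 0.4, 1.9)) {
    direct <- (y0 / 2) * (exp(-S * eta) * cos(C * eta - om * t) +
                          exp(-C * eta) * cos(S * eta + om * t))
    expect_equal(end_driven_solution(eta, t, y0, om), direct,
                 tolerance = 1e-12)
  }
  # amplitude envelope at eta = 8 is below 5% of y0
  ts <- seq(0, 2 * pi / om, length.out = 400)
  expect_lt(max(abs(end_driven_solution(8, ts, y0, om))), 0.05 * y0)
})

test_that("middle-driven solution equals the four-term form and is an
          even function of position", {
  y0 <- 2e-6; om <- 1.3
  C <- cos(pi / 8); S <- sin(pi / 8)
  eta <- seq(0, 6, by = 0.23)
  for (t in c(0, 0.7)) {
    direct <- (y0 / 2) * (
      exp(-S * eta) * (cos(C * eta - om * t) + sin(C * eta - om * t)) +
      exp(-C * eta) * (cos(S * eta + om * t) + sin(S * eta + om * t)))
    expect_equal(middle_driven_solution(eta, t, y0, om), direct,
                 tolerance = 1e-12)
  }
  expect_equal(middle_driven_solution(0, 0, y0, om), y0)
  # both arms of the contour carry the same profile (same |eta|)
  expect_equal(middle_driven_solution(abs(-2.4), 0.7, y0, om),
               middle_driven_solution(2.4, 0.7, y0, om))
  expect_lt(abs(middle_driven_solution(80, 0.2, y0, om)), 1e-12 * y0)
})

test_that("rod model keeps kappa and persistence length consistent", {
  rod <- rod_model(kappa = 6e-24, contour_length = 20e-6, diameter = 60e-9,
                   medium_viscosity = 0.05, temperature = 296)
  expect_equal(rod$persistence_length * kB * rod$temperature, rod$kappa,
               tolerance = 1e-12)
  rod2 <- rod_model(persistence_length = rod$persistence_length,
                    contour_length = 20e-6, diameter = 60e-9,
                    medium_viscosity = 0.05, temperature = 296)
  expect_equal(rod2$kappa, rod$kappa, tolerance = 1e-12)
  expect_gt(rod$zeta, 0)
  expect_error(rod_model(kappa = 1e-24, persistence_length = 1,
                         contour_length = 1e-6, diameter = 1e-8,
                         medium_viscosity = 1e-3), "exactly one")
  expect_error(rod_model(kappa = 1e-24, contour_length = 1e-8,
                         diameter = 1e-6, medium_viscosity = 1e-3),
               "contour_length > diameter")
})

test_that("the closed-form solution satisfies the bending PDE under grid
          refinement", {
  y0 <- 1e-6; om <- 2
  residual <- function(h) {
    eta <- seq(0.5, 6, by = h)      # interior points
    t0 <- 0.37; ht <- h^2           # refine time faster: dominant error O(h^2)
    yt <- (end_driven_solution(eta, t0 + ht, y0, om) -
           end_driven_solution(eta, t0 - ht, y0, om)) / (2 * ht)
    y <- function(e) end_driven_solution(e, t0, y0, om)
    yxxxx <- (y(eta - 2 * h) - 4 * y(eta - h) + 6 * y(eta) -
              4 * y(eta + h) + y(eta + 2 * h)) / h^4
    # nondimensional form: d y/d(omega t) = -d^4 y/d eta^4
    max(abs(yt / om + yxxxx)) / y0
  }
  r1 <- residual(0.1); r2 <- residual(0.05)
  expect_lt(r2, r1)
  expect_lt(r1 / r2, 8)   # ~4 expected for a second-order stencil
  expect_gt(r1 / r2, 2.5)
  expect_lt(r2, 0.01)
})
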