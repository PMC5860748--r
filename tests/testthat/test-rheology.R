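# Power-law fitting, sweep assembly, regime classification, drift test.

test_that("power-law fits recover exact and noisy exponents", {
  x <- seq(0.04, 2.5, length.out = 10)
  pl <- fit_power_law(x, x^-0.25)
  expect_equal(pl$exponent, -0.25, tolerance = 1e-10)
  expect_equal(pl$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit_power_law(x, rep(2, 10))$exponent, 0, tolerance = 1e-12)
  set.seed(12)
  xs <- 10^runif(20, -1, 1)
  ys <- xs^2 * exp(rnorm(20, 0, 0.01))
  expect_equal(fit_power_law(xs, ys)$exponent, 2, tolerance = 0.05)
  expect_error(fit_power_law(c(-1, 1, 2), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(1:2, 1:2), ">= 3")
})

test_that("sweep assembly computes kappa_eff exactly and handles
          duplicates", {
  sw <- synthetic_sweep(-0.25)
  expect_equal(sw$records$kappa_eff,
               sw$records$l_omega^4 * sw$records$omega, tolerance = 1e-12)
  # quarter-power sweep: constant kappa_eff
  expect_lt(diff(range(sw$records$kappa_eff)) /
              mean(sw$records$kappa_eff), 1e-10)
  # constant l_omega: kappa_eff proportional to omega
  sw0 <- synthetic_sweep(0)
  pl <- fit_power_law(sw0$records$omega, sw0$records$kappa_eff)
  expect_equal(pl$exponent, 1, tolerance = 1e-10)
  # kappa in J·m appears when zeta is known
  rod <- small_rod()
  fits <- attr(synthetic_sweep(-0.25), "fits")
  sw2 <- build_sweep(lapply(seq_len(nrow(sw$records)), function(i)
    structure(list(l_omega = sw$records$l_omega[i], y0_fit = 1e-6,
                   x0 = 0, phase = 0, omega = sw$records$omega[i],
                   frequency_hz = sw$records$frequency_hz[i],
                   drive_point = "end", mode = "complex",
                   residual_norm = 0, covariance = matrix(0, 4, 4),
                   par_names = letters[1:4], se_l_omega = 0,
                   n_points = 10L, flags = character(0)),
              class = "hydro_fit")), rod = rod)
  expect_equal(sw2$records$kappa, rod$zeta * sw2$records$kappa_eff)
  # duplicated frequencies collapse with a warning
  dup <- c(attr(sw, "fits"), attr(sw, "fits"))
  fits_l <- lapply(seq_len(nrow(sw$records))[c(1, 1, 2, 3)], function(i)
    structure(list(l_omega = sw$records$l_omega[i], y0_fit = 1e-6,
                   x0 = 0, phase = 0, omega = sw$records$omega[i],
                   frequency_hz = sw$records$frequency_hz[i],
                   drive_point = "end", mode = "complex",
                   residual_norm = 0, covariance = matrix(0, 4, 4),
                   par_names = letters[1:4], se_l_omega = 0,
                   n_points = 10L, flags = character(0)),
              class = "hydro_fit"))
  expect_warning(sw3 <- build_sweep(fits_l), "duplicate")
  expect_identical(nrow(sw3$records), 3L)
})

test_that("regime classification separates wormlike-chain from
          shear-coupled wormlike-bundle scaling", {
  expect_identical(classify_regime(synthetic_sweep(-0.25))$model_kind,
                   "WLC_constant")
  # l_omega ~ omega^(-1/2)  =>  kappa_eff ~ l_omega^2
  cls <- classify_regime(synthetic_sweep(-0.5))
  expect_identical(cls$model_kind, "WLB_shear_coupled")
  expect_equal(cls$exponent_kappa_l, 2, tolerance = 1e-6)
  expect_identical(classify_regime(synthetic_sweep(-0.45))$model_kind,
                   "free_power_law")
  # too few frequencies: indeterminate, never a silent default
  sw3 <- synthetic_sweep(-0.25, frequencies = c(0.1, 0.5, 2))
  expect_identical(classify_regime(sw3)$model_kind, "indeterminate")
  # sub-decade span classifies but carries a low-power flag
  swn <- synthetic_sweep(-0.25,
                         frequencies = seq(0.2, 1.0, length.out = 5))
  cln <- classify_regime(swn)
  expect_true("low_power" %in% cln$flags)
})

test_that("the kappa-omega exponent identity 4a+1 holds on noisy sweeps
          and classification is unit-invariant", {
  for (seed in 1:5) {
    a_true <- runif(1, -0.6, 0.1)
    sw <- synthetic_sweep(a_true, noise_sd = 0.02, seed = seed)
    a <- fit_power_law(sw$records$omega, sw$records$l_omega)
    b <- fit_power_law(sw$records$omega, sw$records$kappa_eff)
    expect_equal(b$exponent, 4 * a$exponent + 1,
                 tolerance = 1e-8)  # algebraic identity, exact in OLS
    # unit rescaling changes prefactors only
    sw_scaled <- sw
    sw_scaled$records$l_omega <- sw$records$l_omega * 1e6
    sw_scaled$records$omega <- sw$records$omega / (2 * pi)
    sw_scaled$records$kappa_eff <- sw_scaled$records$l_omega^4 *
      sw_scaled$records$omega
    c1 <- classify_regime(sw); c2 <- classify_regime(sw_scaled)
    expect_identical(c1$model_kind, c2$model_kind)
    expect_equal(c1$exponent_l_omega, c2$exponent_l_omega,
                 tolerance = 1e-9)
  }
})

test_that("the long-time stability check reports drift correctly", {
  set.seed(9)
  tt <- seq(0, 600, by = 30)
  flat <- drift_test(tt, 4e-6 * exp(rnorm(length(tt), 0, 0.01)))
  expect_gt(flat$p_value, 0.01)
  expect_lt(abs(flat$relative_drift), 0.05)
  trending <- drift_test(tt, 4e-6 * (1 + 0.001 * tt))
  expect_lt(trending$p_value, 1e-6)
  expect_equal(trending$relative_drift, 0.6 / 1.3, tolerance = 0.05)
})
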