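# Shared synthetic fixtures, built in code and cached per test run.
# "Small" fixtures use a 128x64 px field of view and a 10 µm bundle so a
# full render-track-fit cycle stays well under a second of CPU.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

small_rod <- function(kappa = 6e-24) {
  rod_model(kappa = kappa, contour_length = 10e-6, diameter = 60e-9,
            medium_viscosity = 0.05)
}

small_img <- function(seed = 1L, noiseless = FALSE, ...) {
  args <- list(nx = 128L, ny = 64L, rng_seed = seed, ...)
  if (noiseless) {
    args$shot_noise <- FALSE
    args$read_noise_sd <- 0
    args$bleach_rate <- 0
  }
  do.call(imaging_config, args)
}

small_stack <- function(frequency_hz = 1, seed = 1L, noiseless = FALSE,
                        n_periods = 5, amplitude = 1e-6, ...) {
  drv <- drive_protocol(amplitude = amplitude,
                        frequency_hz = frequency_hz,
                        n_periods = n_periods)
  render_stack(small_rod(), drv, small_img(seed, noiseless, ...))
}

# default-SNR and noiseless stacks reused across test files
noisy_fixture <- function() fixture("noisy", function() small_stack(seed = 11L))
clean_fixture <- function() fixture("clean", function()
  small_stack(noiseless = TRUE))

# tracked-vs-truth RMS error in pixel units, over samples valid in both
tracking_rms_px <- function(kymo, truth, pixel_size) {
  both <- kymo$valid & truth$valid
  sqrt(mean((kymo$y[both] - truth$y[both])^2)) / pixel_size
}

analyze_fixture <- function(stack, ...) {
  analyze_stack(stack, keep_intermediates = TRUE, ...)
}

# synthetic amplitude profile straight from the closed-form model
analytic_profile <- function(l_omega = 5e-6, y0 = 1e-6, x0 = 0, phi = 0,
                             drive_point = "end",
                             x = seq(0.5e-6, 25e-6, by = 0.25e-6),
                             omega = 2 * pi) {
  eta <- pmax(x - x0, 0) / l_omega
  cv <- steady_amplitude(eta, y0, drive_point) * exp(1i * phi)
  structure(list(x = x, amplitude = Mod(cv), phase = Arg(cv), cvalue = cv,
                 n_periods_used = 3L, omega = omega,
                 frequency_hz = omega / (2 * pi), drive_point = drive_point),
            class = "amplitude_profile")
}

# sweep built from exact power-law l_omega values (no imaging)
synthetic_sweep <- function(l_exponent, frequencies = default_frequencies(),
                            prefactor = 4e-6, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  omega <- 2 * pi * frequencies
  l <- prefactor * (omega / omega[1])^l_exponent
  if (noise_sd > 0) l <- l * exp(rnorm(length(l), 0, noise_sd))
  fits <- lapply(seq_along(omega), function(i) {
    structure(list(l_omega = l[i], y0_fit = 1e-6, x0 = 0, phase = 0,
                   omega = omega[i], frequency_hz = frequencies[i],
                   drive_point = "end", mode = "complex",
                   residual_norm = 0,
                   covariance = matrix(0, 4, 4),
                   par_names = c("log_l", "log_y0", "x0", "phi"),
                   se_l_omega = 0, n_points = 100L,
                   flags = character(0)),
              class = "hydro_fit")
  })
  build_sweep(fits)
}
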