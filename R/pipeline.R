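# End-to-end pipeline: simulate -> track -> band-pass -> fit -> sweep.
# Each stage is a pure function of its (persistable) input, so any stage
# can be re-run from intermediates.

#' Log-spaced drive frequencies of the standard sweep protocol
#'
#' @param n Number of frequencies.
#' @param fmin,fmax Frequency range in Hz (default 0.04–2.5 Hz, the range
#'   accessible between camera exposure limits and photobleaching).
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n = 8, fmin = 0.04, fmax = 2.5) {
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

#' Default rod model of a thin depletion-bundled actin bundle
#'
#' A thin methyl-cellulose-bundled actin bundle: bending stiffness
#' 6e-24 J·m (persistence length ~1.5 mm, consistent with a few tens of
#' coupled actin filaments), 20 µm contour, 60 nm diameter, in a 50 mPa·s
#' methyl-cellulose medium.  With these values the hydrodynamic length
#' runs from ~4 µm (0.04 Hz) down to ~1.4 µm (2.5 Hz).
#'
#' @param kappa Bending stiffness in J·m.
#' @param ... Passed to [rod_model()].
#' @return A [rod_model()].
#' @export
default_rod <- function(kappa = 6e-24, ...) {
  args <- list(kappa = kappa, contour_length = 20e-6, diameter = 60e-9,
               medium_viscosity = 0.05)
  args[names(list(...))] <- list(...)
  do.call(rod_model, args)
}

#' Analyze one recording: stack in, hydrodynamic-length fit out
#'
#' Chains [preprocess_stack()], [smooth_and_enhance()], [track_contour()],
#' [bandpass()] and [fit_hydrodynamic_length()].
#'
#' @param stack A `frame_stack`.
#' @param rotation_angle Passed to [preprocess_stack()] (`0` for stacks
#'   straight out of [render_stack()]; `NULL` estimates it).
#' @param crop_halfwidth Optional crop band half-width in m.
#' @param sigma_x,edge_sigma Filter scales in px, see
#'   [smooth_and_enhance()].
#' @param window,bead_exclusion_radii Tracking options, see
#'   [track_contour()].
#' @param mode Fit mode, see [fit_hydrodynamic_length()].
#' @param keep_intermediates If `TRUE`, attach the kymograph and
#'   amplitude profile to the returned fit.
#' @return A `hydro_fit`.
#' @export
analyze_stack <- function(stack, rotation_angle = 0, crop_halfwidth = NULL,
                          sigma_x = 1, edge_sigma = 1, window = 5L,
                          bead_exclusion_radii = 2,
                          mode = c("complex", "envelope"),
                          keep_intermediates = FALSE) {
  mode <- match.arg(mode)
  pp <- preprocess_stack(stack, rotation_angle = rotation_angle,
                         crop_halfwidth = crop_halfwidth)
  sm <- smooth_and_enhance(pp, sigma_x = sigma_x, edge_sigma = edge_sigma)
  kymo <- track_contour(sm, window = window,
                        bead_exclusion_radii = bead_exclusion_radii)
  prof <- bandpass(kymo)
  fit <- fit_hydrodynamic_length(prof, mode = mode)
  if (keep_intermediates) {
    fit$kymograph <- kymo
    fit$profile <- prof
  }
  fit
}

#' Simulate and analyze a full frequency sweep
#'
#' Renders one seeded recording per frequency for a given rod, pushes
#' each through the tracking and fitting pipeline, and assembles the
#' sweep.  Per-frequency seeds are derived deterministically from `seed`.
#'
#' @param rod A [rod_model()].
#' @param frequencies Drive frequencies in Hz.
#' @param amplitude Drive amplitude in m.
#' @param img Base [imaging_config()]; its `rng_seed` is overridden per
#'   frequency.
#' @param seed Integer master seed.
#' @param n_periods Periods recorded per frequency.
#' @param drive_point `"end"` or `"middle"`.
#' @param mode Fit mode passed to [analyze_stack()].
#' @param bundle_label Label stored in the sweep.
#' @return A `sweep_result` with the per-frequency `hydro_fit`s attached
#'   as attribute `"fits"` and the true `l_omega` per frequency as column
#'   `l_omega_true` of `records`.
#' @export
run_sweep <- function(rod, frequencies = default_frequencies(),
                      amplitude = 1e-6, img = imaging_config(),
                      seed = 1L, n_periods = 5,
                      drive_point = "end",
                      mode = c("complex", "envelope"),
                      bundle_label = "") {
  mode <- match.arg(mode)
  fits <- vector("list", length(frequencies))
  l_true <- numeric(length(frequencies))
  for (i in seq_along(frequencies)) {
    drv <- drive_protocol(amplitude = amplitude,
                          frequency_hz = frequencies[i],
                          drive_point = drive_point,
                          n_periods = n_periods)
    img_i <- img
    img_i$rng_seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    stack <- render_stack(rod, drv, img_i)
    l_true[i] <- stack$l_omega_true
    fits[[i]] <- analyze_stack(stack, mode = mode)
  }
  sweep <- build_sweep(fits, rod = rod, bundle_label = bundle_label)
  sweep$records$l_omega_true <- l_true[match(sweep$records$frequency_hz,
                                             frequencies)]
  attr(sweep, "fits") <- fits
  sweep
}
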