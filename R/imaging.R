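# Synthetic fluorescence renderer: a TRITC-labelled bundle as a Gaussian
# line profile, a saturated bead disk at the driven point, exposure-window
# motion blur, exponential photobleaching, Poisson shot noise and Gaussian
# read noise.  Every stochastic render is seeded and ships its own ground
# truth.

#' Camera and optics configuration for the synthetic renderer
#'
#' Defaults emulate a 100x fluorescence setup: 100 nm pixels, a 150 nm
#' (sigma) point-spread function, and a 16-bit CCD.  Bundles are
#' sub-resolution, so bundle thickness enters rendering only through line
#' brightness, never through a resolvable width.
#'
#' @param pixel_size Pixel size in m/px.
#' @param psf_sigma Gaussian PSF sigma in m (>= pixel_size / 2).
#' @param nx,ny Frame width and height in px.
#' @param photons_per_pixel_peak Expected peak signal photons per pixel at
#'   the bundle centerline, first frame.
#' @param background_level Expected background photons per pixel.
#' @param bleach_rate Photobleaching rate in 1/s; applied to the signal
#'   (and the bead), not the background.
#' @param bead_radius Bead radius in m (2 µm diameter beads by default).
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param shot_noise If `FALSE`, Poisson sampling is disabled; together
#'   with `read_noise_sd = 0` this yields deterministic noiseless frames.
#' @param exposure_subsamples Time points per exposure window used to
#'   integrate motion blur (>= 8 advised: at high drive frequency a 50 ms
#'   exposure spans a noticeable fraction of a period).
#' @param margin_px Columns between the left image edge and the driven
#'   end of the bundle.
#' @param rng_seed Integer seed; a fixed seed makes renders bitwise
#'   identical.
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 100e-9, psf_sigma = 150e-9,
                           nx = 256L, ny = 128L,
                           photons_per_pixel_peak = 150,
                           background_level = 20, bleach_rate = 0.002,
                           bead_radius = 1e-6, read_noise_sd = 3,
                           shot_noise = TRUE, exposure_subsamples = 8L,
                           margin_px = 12L, rng_seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (psf_sigma < pixel_size / 2)
    stop("psf_sigma below pixel_size/2 cannot be rendered faithfully")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (photons_per_pixel_peak < 0 || background_level < 0 || read_noise_sd < 0)
    stop("photon and noise levels must be >= 0")
  structure(list(
    pixel_size = pixel_size, psf_sigma = psf_sigma,
    nx = as.integer(nx), ny = as.integer(ny),
    photons_per_pixel_peak = photons_per_pixel_peak,
    background_level = background_level, bleach_rate = bleach_rate,
    bead_radius = bead_radius, read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    exposure_subsamples = as.integer(exposure_subsamples),
    margin_px = as.integer(margin_px), rng_seed = as.integer(rng_seed)
  ), class = "imaging_config")
}

# run `expr` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# geometry shared by renderer and truth bookkeeping; all positions in m,
# pixel centers at (index - 1) * pixel_size (0-based index convention)
stack_geometry <- function(rod, drive, img) {
  l_omega <- hydrodynamic_length(rod$kappa, rod$zeta, drive$omega)
  fov_x <- img$nx * img$pixel_size
  if (fov_x < 6 * l_omega)
    stop(sprintf(
      "field of view (%.3g m) shorter than 6 l_omega (l_omega = %.3g m)",
      fov_x, l_omega))
  x_img <- (seq_len(img$nx) - 1) * img$pixel_size
  x0 <- img$margin_px * img$pixel_size        # driven end / bead center
  if (drive$drive_point == "end") {
    x_rod <- x_img - x0
    on_rod <- x_rod >= 0 & x_rod <= rod$contour_length
    eta <- pmax(x_rod, 0) / l_omega
  } else {                                    # bead at the rod middle
    xc <- x0 + rod$contour_length / 2
    x_rod <- x_img - x0
    on_rod <- x_rod >= 0 & x_rod <= rod$contour_length
    eta <- abs(x_img - xc) / l_omega
    x0 <- xc
  }
  list(l_omega = l_omega, x_img = x_img, x_drive = x0, on_rod = on_rod,
       eta = eta, row0 = (img$ny - 1) / 2)
}

#' Render a synthetic image stack of a driven bundle
#'
#' Produces a seeded fluorescence time series with known ground truth.
#' Each frame integrates the analytic contour ([steady_amplitude()]) over
#' the exposure window, draws the bundle as a Gaussian line profile of
#' width `psf_sigma`, adds the bead as a saturated disk riding the driven
#' point, applies exponential photobleaching to the signal, then Poisson
#' shot noise and Gaussian read noise, and quantizes to 16-bit counts.
#'
#' Frame timestamps are the exposure midpoints, so motion blur is
#' symmetric about the stored time and introduces no phase bias.
#'
#' @param rod A [rod_model()].
#' @param drive A [drive_protocol()].
#' @param img An [imaging_config()].
#' @return Object of class `frame_stack`: list with `frames` (ny x nx x
#'   n_frames array of counts), `times` (exposure midpoints, s), `config`,
#'   `drive`, `rod`, and `truth` (a [kymograph()] of the noise-free
#'   contour at frame times).
#' @export
render_stack <- function(rod, drive, img = imaging_config()) {
  stopifnot(inherits(rod, "rod_model"), inherits(drive, "drive_protocol"),
            inherits(img, "imaging_config"))
  g <- stack_geometry(rod, drive, img)
  nt <- drive$n_frames
  if (nt < 3) stop("drive protocol yields fewer than 3 frames")
  px <- img$pixel_size
  sig2 <- 2 * (img$psf_sigma / px)^2           # PSF variance in px^2
  rows <- seq_len(img$ny) - 1                  # 0-based row centers
  Y <- steady_amplitude(g$eta, drive$amplitude, drive$drive_point)
  Yb <- steady_amplitude(0, drive$amplitude, drive$drive_point)
  t_start <- (seq_len(nt) - 1) * drive$frame_interval
  t_mid <- t_start + drive$exposure / 2
  nsub <- img$exposure_subsamples
  t_sub <- (seq_len(nsub) - 0.5) / nsub * drive$exposure
  bead_r_px <- img$bead_radius / px
  bead_cols <- which(abs(g$x_img - g$x_drive) <= img$bead_radius)
  bead_dx2 <- ((g$x_img[bead_cols] - g$x_drive) / px)^2
  bead_peak <- 6 * img$photons_per_pixel_peak  # saturates after quantization

  frames <- array(0, dim = c(img$ny, img$nx, nt))
  signal_cols <- which(g$on_rod)
  Yr <- Y[signal_cols]
  render_one <- function(k) {
    acc <- matrix(0, img$ny, img$nx)
    for (ts in t_start[k] + t_sub) {
      defl <- Re(Yr * exp(-1i * drive$omega * ts)) / px  # px units
      ctr <- g$row0 + defl
      acc[, signal_cols] <- acc[, signal_cols] +
        img$photons_per_pixel_peak *
          exp(-(outer(rows, ctr, "-"))^2 / sig2)
      # bead disk, riding the driven point
      bd <- g$row0 + Re(Yb * exp(-1i * drive$omega * ts)) / px
      for (j in seq_along(bead_cols)) {
        half <- bead_r_px^2 - bead_dx2[j]
        if (half > 0) {
          half <- sqrt(half)
          rr <- rows >= bd - half & rows <= bd + half
          acc[rr, bead_cols[j]] <- acc[rr, bead_cols[j]] + bead_peak
        }
      }
    }
    acc / nsub
  }

  expected <- vapply(seq_len(nt), render_one,
                     matrix(0, img$ny, img$nx))
  bleach <- exp(-img$bleach_rate * t_mid)
  noisy <- with_seed(img$rng_seed, {
    out <- array(0, dim = dim(expected))
    for (k in seq_len(nt)) {
      lam <- expected[, , k] * bleach[k] + img$background_level
      cnt <- if (img$shot_noise) {
        matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
      } else lam
      if (img$read_noise_sd > 0)
        cnt <- cnt + matrix(rnorm(length(lam), 0, img$read_noise_sd),
                            nrow(lam), ncol(lam))
      out[, , k] <- pmin(pmax(round(cnt), 0), 65535)
    }
    out
  })

  truth_y <- outer(exp(-1i * drive$omega * t_mid), Y)  # nt x nx complex
  truth <- kymograph(
    y = g$row0 * px + Re(truth_y),
    x = g$x_img, times = t_mid,
    valid = matrix(rep(g$on_rod, each = nt), nt, img$nx),
    excluded_cols = integer(0), pixel_size = px,
    drive = drive)

  structure(list(frames = noisy, times = t_mid, config = img,
                 drive = drive, rod = rod, truth = truth,
                 l_omega_true = g$l_omega, x_drive = g$x_drive),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px (%.3g Hz drive, %s)\n",
              d[3], d[2], d[1], x$drive$frequency_hz, x$drive$drive_point))
  invisible(x)
}
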