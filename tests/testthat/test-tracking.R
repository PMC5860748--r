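# Contour tracking: subpixel localization, preprocessing geometry, and
# truth-referenced accuracy.

test_that("subpixel peak localization is exact on symmetric profiles and
          unbiased on subpixel shifts", {
  prof <- 10 + 100 * exp(-((0:63) - 17)^2 / (2 * 1.5^2))
  r <- fit_deflection(prof, background = 10)
  expect_true(r$valid)
  expect_equal(r$center, 17, tolerance = 0.05)
  for (sh in seq(0.1, 0.9, by = 0.2)) {
    p <- 10 + 100 * exp(-((0:63) - (17 + sh))^2 / (2 * 1.5^2))
    r <- fit_deflection(p, background = 10)
    expect_equal(r$center - 17, sh, tolerance = 0.05)
  }
})

test_that("columns without a detectable peak are flagged, not fabricated", {
  expect_false(fit_deflection(rep(7, 64))$valid)
  set.seed(2)
  expect_false(fit_deflection(rnorm(64, 100, 1))$valid)  # no real line
})

test_that("among multiple peaks the one nearest the previous position
          wins", {
  prof <- 5 + 80 * exp(-((0:63) - 20)^2 / 4) + 100 * exp(-((0:63) - 45)^2 / 4)
  expect_equal(fit_deflection(prof, background = 5)$center, 45,
               tolerance = 0.1)  # no hint: global max
  expect_equal(fit_deflection(prof, background = 5, center_hint = 22)$center,
               20, tolerance = 0.1)
})

test_that("tracking is equivariant under whole-pixel shifts of the stack", {
  st <- clean_fixture()
  k1 <- track_contour(st)
  shifted <- st
  shift <- 3L
  d <- dim(st$frames)
  shifted$frames <- st$frames[c((d[1] - shift + 1):d[1], 1:(d[1] - shift)), , ,
                              drop = FALSE]
  k2 <- track_contour(shifted)
  both <- k1$valid & k2$valid
  # ignore rows wrapped through the border
  core <- which(colSums(both) > 0)
  dy <- (k2$y[, core] - k1$y[, core])[both[, core]]
  expect_equal(unique(round(dy / st$config$pixel_size, 6)), shift)
})

test_that("a tilted bundle is straightened by rotation preprocessing", {
  # static synthetic rod at 3 degrees through the image center
  ny <- 96L; nx <- 96L; angle <- 3 * pi / 180
  rows <- (seq_len(ny) - 1); ctr <- (ny - 1) / 2
  frame <- sapply(seq_len(nx) - 1, function(c)
    200 * exp(-((rows - (ctr + tan(angle) * (c - (nx - 1) / 2)))^2) / 4.5))
  st <- structure(list(
    frames = array(rep(frame, 3), dim = c(ny, nx, 3)),
    times = (0:2) * 0.1,
    config = imaging_config(nx = nx, ny = ny, background_level = 0,
                            shot_noise = FALSE, read_noise_sd = 0),
    drive = NULL, rod = NULL, truth = NULL, x_drive = NULL),
    class = "frame_stack")
  expect_equal(estimate_rotation(st), angle, tolerance = 0.002)
  pp <- preprocess_stack(st)   # angle estimated internally
  expect_lt(abs(estimate_rotation(pp)), 0.3 * pi / 180)
})

test_that("a crop band narrower than the drive amplitude is rejected", {
  st <- clean_fixture()
  expect_error(preprocess_stack(st, rotation_angle = 0,
                                crop_halfwidth = 0.5e-6),
               "amplitude")
  pp <- preprocess_stack(st, rotation_angle = 0, crop_halfwidth = 2.5e-6)
  expect_lt(dim(pp$frames)[1], dim(st$frames)[1])
  # tracked positions remain in absolute coordinates after cropping
  k0 <- track_contour(st)
  k1 <- track_contour(pp)
  both <- k0$valid & k1$valid
  expect_lt(max(abs(k0$y[both] - k1$y[both])) / st$config$pixel_size, 0.3)
})

test_that("smoothing and enhancement preserve a flat field and raise the
          line SNR", {
  flat <- structure(list(
    frames = array(50, dim = c(32, 48, 2)), times = c(0, 1),
    config = imaging_config(nx = 48, ny = 32), drive = NULL,
    rod = NULL, truth = NULL, x_drive = NULL), class = "frame_stack")
  sm <- smooth_and_enhance(flat)
  expect_equal(sm$frames[5:28, 5:44, 1],
               matrix(0, 24, 40) + sm$frames[16, 24, 1], tolerance = 1e-6)
  st <- noisy_fixture()
  sm2 <- smooth_and_enhance(preprocess_stack(st, rotation_angle = 0))
  # peak-to-background-sd ratio on the central rod column
  snr <- function(fr) {
    col <- fr[, 60]
    (max(col) - median(col)) / mad(fr[1:10, ])
  }
  expect_gt(snr(sm2$frames[, , 1]), snr(st$frames[, , 1]))
  expect_error(smooth_and_enhance(flat, sigma_x = 100), "larger")
})

test_that("noiseless and default-SNR tracking meet the truth-referenced
          accuracy targets without bias", {
  st0 <- clean_fixture()
  k0 <- track_contour(smooth_and_enhance(
    preprocess_stack(st0, rotation_angle = 0)))
  expect_lt(tracking_rms_px(k0, st0$truth, st0$config$pixel_size), 0.2)

  st1 <- noisy_fixture()
  k1 <- track_contour(smooth_and_enhance(
    preprocess_stack(st1, rotation_angle = 0)))
  expect_lt(tracking_rms_px(k1, st1$truth, st1$config$pixel_size), 0.5)
  # zero mean residual within its standard error
  both <- k1$valid & st1$truth$valid
  resid <- (k1$y[both] - st1$truth$y[both]) / st1$config$pixel_size
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
  # bead vicinity is excluded
  expect_true(length(k1$excluded_cols) > 0)
  expect_true(all(abs(k1$x[k1$excluded_cols] - st1$x_drive) <=
                    2 * st1$config$bead_radius + 1e-12))
  expect_true(all(is.na(k1$y[, k1$excluded_cols])))
})
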