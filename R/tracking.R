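# Contour tracking: recover the transverse deflection y(x, t) of the
# bundle from an image stack.  Pipeline: geometric preprocessing (rotate
# the deflection axis onto image y, crop to the anticipated amplitude
# band), mild x-smoothing plus a horizontal-line-enhancing filter in y,
# then per-column subpixel peak localization.
#
# Coordinate conventions (fixed for truth comparison): pixel indices are
# 0-based, positions are pixel centers, x increases away from the driven
# end, y positions are absolute image coordinates in meters.

#' Space-time deflection matrix of a tracked bundle
#'
#' Container for y(x, t): one row per frame, one column per x position.
#' `y` holds absolute transverse positions in m (pixel center convention,
#' row index 0 at y = 0); untracked samples are `NA` and flagged in
#' `valid`.
#'
#' @param y Numeric matrix (time x position), m.
#' @param x Positions along the bundle in m.
#' @param times Frame times in s.
#' @param quality Per-sample fit diagnostic (residual of the peak fit);
#'   same shape as `y`.
#' @param valid Logical matrix, same shape as `y`.
#' @param excluded_cols Integer indices of columns excluded from analysis
#'   (e.g. the bead vicinity).
#' @param pixel_size Pixel size in m.
#' @param drive Optional [drive_protocol()] metadata.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(y, x, times, quality = NULL, valid = NULL,
                      excluded_cols = integer(0), pixel_size = NA_real_,
                      drive = NULL) {
  y <- as.matrix(y)
  if (length(x) != ncol(y) || length(times) != nrow(y))
    stop("kymograph dimensions inconsistent: y must be time x position")
  if (is.null(valid)) valid <- !is.na(y)
  if (is.null(quality)) quality <- matrix(0, nrow(y), ncol(y))
  if (any(!is.finite(quality[valid]))) stop("quality must be finite where valid")
  if (length(excluded_cols)) valid[, excluded_cols] <- FALSE
  y[!valid] <- NA_real_
  structure(list(y = y, x = x, times = times, quality = quality,
                 valid = valid, excluded_cols = sort(unique(excluded_cols)),
                 pixel_size = pixel_size, drive = drive),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%d excluded columns)\n",
              nrow(x$y), ncol(x$y), length(x$excluded_cols)))
  invisible(x)
}

#' @export
as.data.frame.kymograph <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$y)),
    x = rep(x$x, each = nrow(x$y)),
    y = as.vector(x$y),
    quality = as.vector(x$quality),
    excluded = rep(seq_len(ncol(x$y)) %in% x$excluded_cols,
                   each = nrow(x$y)),
    valid = as.vector(x$valid))
}

# intensity-weighted centroid of each column of one frame (rows 0-based);
# used for rotation estimation and renderer validation
column_centroids <- function(frame, background = NULL) {
  if (is.null(background)) background <- median(frame)
  w <- pmax(frame - background, 0)
  tot <- colSums(w)
  ctr <- colSums(w * (seq_len(nrow(frame)) - 1)) / tot
  ctr[tot <= 0 | tot < 3 * background] <- NA_real_
  ctr
}

#' Estimate the residual tilt of the undisturbed bundle
#'
#' Regresses the intensity centroid row of each column on the column
#' index in a single frame; the arctangent of the slope is the angle (in
#' rad) by which the stack should be rotated so the undisturbed contour
#' runs along x.
#'
#' @param stack A `frame_stack`.
#' @param frame_index Frame to use (ideally an undisturbed one).
#' @return Angle in rad.
#' @export
estimate_rotation <- function(stack, frame_index = 1L) {
  fr <- stack$frames[, , frame_index]
  ctr <- column_centroids(fr)
  ok <- is.finite(ctr)
  if (sum(ok) < 8) stop("too few columns with signal to estimate rotation")
  cols <- (seq_along(ctr) - 1)[ok]
  atan(unname(coef(stats::lm(ctr[ok] ~ cols))[2]))
}

#' Rotate and crop a stack so deflection lies along image y
#'
#' Rotates every frame by `-rotation_angle` (bilinear interpolation, via
#' EBImage) so the undisturbed contour runs along x, then crops rows to a
#' band of `crop_halfwidth` (the largest anticipated amplitude) about the
#' contour.  The removed row offset is recorded so tracked positions stay
#' in absolute coordinates.
#'
#' @param stack A `frame_stack`.
#' @param rotation_angle Tilt of the undisturbed contour in rad, or
#'   `NULL` to estimate it with [estimate_rotation()].
#' @param crop_halfwidth Half-height of the retained band in m, or `NULL`
#'   to keep all rows.  Must exceed the drive amplitude when the drive is
#'   known.
#' @return A `frame_stack` with rotated/cropped frames and an added
#'   `row_offset_px` field (0-based global index of local row 0).
#' @export
preprocess_stack <- function(stack, rotation_angle = NULL,
                             crop_halfwidth = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(rotation_angle)) rotation_angle <- estimate_rotation(stack)
  frames <- stack$frames
  nt <- dim(frames)[3]
  if (abs(rotation_angle) > 1e-9) {
    deg <- -rotation_angle * 180 / pi
    bg <- stack$config$background_level
    for (k in seq_len(nt)) {
      # EBImage images are (x, y): transpose in, transpose out
      rot <- EBImage::rotate(t(frames[, , k]), deg, filter = "bilinear",
                             output.dim = dim(t(frames[, , k])),
                             bg.col = bg)
      frames[, , k] <- t(rot)
    }
  }
  row_offset <- 0L
  if (!is.null(crop_halfwidth)) {
    if (!is.null(stack$drive) && crop_halfwidth < stack$drive$amplitude)
      stop(sprintf(
        "crop_halfwidth (%.3g m) below the drive amplitude (%.3g m)",
        crop_halfwidth, stack$drive$amplitude))
    px <- stack$config$pixel_size
    mean_img <- rowMeans(frames, dims = 2)
    ctr_row <- stats::median(column_centroids(mean_img), na.rm = TRUE)
    half_px <- ceiling(crop_halfwidth / px)
    lo <- max(1L, floor(ctr_row + 1 - half_px))
    hi <- min(dim(frames)[1], ceiling(ctr_row + 1 + half_px))
    band <- frames[lo:hi, , , drop = FALSE]
    if (max(band) < stack$config$background_level +
        4 * sqrt(stack$config$background_level + 1))
      stop("crop band contains no contour signal above background")
    frames <- band
    row_offset <- lo - 1L
  }
  out <- stack
  out$frames <- frames
  out$row_offset_px <- row_offset + (stack$row_offset_px %||% 0L)
  out$rotation_applied <- rotation_angle
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sampled, unit-sum Gaussian kernel
gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth along x and enhance horizontal line features
#'
#' Applies the tracker's preprocessing filter to every frame: a marginal
#' Gaussian smoothing along x combined with a horizontal-line-emphasizing
#' filter along y (negated second derivative of a Gaussian, a ridge
#' filter with positive response on bright lines running along x).
#' Negative responses are clamped to zero.
#'
#' @param stack A `frame_stack`.
#' @param sigma_x Gaussian sigma along x in px.
#' @param edge_sigma Scale of the ridge filter along y in px; 0 disables
#'   the enhancement, leaving pure x-smoothing.
#' @return The stack with filtered frames.
#' @export
smooth_and_enhance <- function(stack, sigma_x = 1, edge_sigma = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  kx <- gauss_kernel(sigma_x)
  ky <- if (edge_sigma > 0) {
    h <- max(2L, ceiling(3 * edge_sigma))
    u <- seq(-h, h)
    g <- exp(-u^2 / (2 * edge_sigma^2))
    k <- -(u^2 / edge_sigma^2 - 1) * g       # -d2/dy2 of Gaussian (shape)
    k <- k - mean(k)                          # zero response on flat field
    k / sum(pmax(k, 0))                       # unit gain on a matched ridge
  } else 1
  K <- outer(ky, kx)
  d <- dim(stack$frames)
  if (nrow(K) > d[1] || ncol(K) > d[2])
    stop("filter kernel larger than the image")
  out <- stack
  for (k in seq_len(d[3])) {
    f <- EBImage::filter2(t(stack$frames[, , k]), t(K),
                          boundary = "replicate")
    out$frames[, , k] <- pmax(t(f), 0)
  }
  out
}

#' Subpixel peak position of a single intensity profile
#'
#' Locates the bundle crossing in one image column: discrete argmax, then
#' a parabola fit to the log of the background-subtracted intensities in
#' a window around it (intensity-squared weights, the standard Gaussian
#' peak estimator), whose vertex gives the subpixel center.  Columns with
#' no peak above background are flagged, never fabricated.
#'
#' @param profile Intensity versus row (one column).
#' @param window Odd fit-window width in px (>= 5 so the quadratic is
#'   overdetermined).
#' @param background Background level; estimated as the profile median if
#'   `NULL`.
#' @param center_hint Optional previous-frame position (0-based rows):
#'   among multiple candidate peaks, the one nearest the hint is chosen.
#' @return List with `center` (0-based row, subpixel), `quality`
#'   (weighted RMS log-residual of the parabola fit) and `valid`.
#' @export
fit_deflection <- function(profile, window = 5L, background = NULL,
                           center_hint = NULL) {
  r <- fit_columns(matrix(profile, ncol = 1), window = window,
                   background = background,
                   prev = if (is.null(center_hint)) NA_real_ else center_hint)
  list(center = r$center[1], quality = r$quality[1], valid = r$valid[1])
}

# Vectorized per-column peak localization for one frame.
# mat: ny x ncol intensity matrix; prev: length-ncol vector of previous
# centers (0-based rows, NA = use global argmax).  Returns 0-based
# subpixel centers.
fit_columns <- function(mat, window = 5L, background = NULL, prev = NA_real_,
                        noise = NULL) {
  ny <- nrow(mat); nc <- ncol(mat)
  if (window %% 2 != 1 || window < 5)
    stop("window must be odd and >= 5 for an overdetermined parabola")
  h <- (window - 1L) %/% 2L
  if (is.null(background)) background <- apply(mat, 2, stats::median)
  background <- rep_len(background, nc)
  if (is.null(noise)) noise <- apply(mat, 2, stats::mad)
  noise <- rep_len(noise, nc)
  thr <- background + pmax(5 * noise, 1e-9)
  prev <- rep_len(prev, nc)

  # candidate peaks: strict local maxima above threshold
  up <- rbind(TRUE, mat[-1, , drop = FALSE] >= mat[-ny, , drop = FALSE])
  dn <- rbind(mat[-ny, , drop = FALSE] > mat[-1, , drop = FALSE], TRUE)
  is_pk <- up & dn & sweep(mat, 2, thr, ">")
  has_pk <- colSums(is_pk) > 0

  rowidx <- matrix(seq_len(ny) - 1, ny, nc)          # 0-based
  # nearest candidate to the hint; global max where no hint
  pen <- abs(rowidx - matrix(prev, ny, nc, byrow = TRUE))
  pen[!is_pk] <- Inf
  use_global <- !is.finite(prev)
  score <- -pen
  gm <- mat; gm[!is_pk] <- -Inf
  score[, use_global] <- gm[, use_global]
  pk <- max.col(t(score), ties.method = "first")     # 1-based row of peak

  # gather window values; clamp window inside the image
  pkc <- pmin(pmax(pk, h + 1L), ny - h)
  off <- seq(-h, h)
  idx <- outer(off, pkc, "+")                        # window x ncol
  V <- matrix(mat[cbind(as.vector(idx), rep(seq_len(nc), each = window))],
              window, nc)
  V <- sweep(V, 2, background, "-")
  pos <- V > 0
  W <- (V * pos)^2                                   # Gaussian-fit weights
  lnV <- ifelse(pos, log(pmax(V, 1e-300)), 0)
  X <- sweep(idx, 2, pk, "-")                        # offsets rel. argmax

  # weighted quadratic fit ln V ~ a x^2 + b x + c, per column (Cramer)
  s0 <- colSums(W);        s1 <- colSums(W * X)
  s2 <- colSums(W * X^2);  s3 <- colSums(W * X^3);  s4 <- colSums(W * X^4)
  t0 <- colSums(W * lnV);  t1 <- colSums(W * X * lnV)
  t2 <- colSums(W * X^2 * lnV)
  det3 <- function(a1,a2,a3,b1,b2,b3,c1,c2,c3)
    a1*(b2*c3-b3*c2) - a2*(b1*c3-b3*c1) + a3*(b1*c2-b2*c1)
  D  <- det3(s4,s3,s2, s3,s2,s1, s2,s1,s0)
  Da <- det3(t2,s3,s2, t1,s2,s1, t0,s1,s0)
  Db <- det3(s4,t2,s2, s3,t1,s1, s2,t0,s0)
  Dc <- det3(s4,s3,t2, s3,s2,t1, s2,s1,t0)
  a <- Da / D; b <- Db / D; cc <- Dc / D

  npos <- colSums(pos)
  ok <- has_pk & npos >= 3 & is.finite(a) & a < -1e-12
  vertex <- -b / (2 * a)
  ok <- ok & is.finite(vertex) & abs(vertex) <= h + 0.5
  center <- (pk - 1) + vertex                        # 0-based subpixel

  fitted <- a[col(X)] * X^2 + b[col(X)] * X + cc[col(X)]
  resid2 <- W * (lnV - fitted)^2
  quality <- sqrt(colSums(resid2) / pmax(s0, 1e-300))
  quality[!ok] <- Inf

  list(center = ifelse(ok, center, NA_real_),
       quality = ifelse(ok, quality, NA_real_), valid = ok)
}

#' Track the bundle contour through an image stack
#'
#' Runs per-column subpixel peak localization ([fit_deflection()]) on
#' every frame of a preprocessed stack and assembles the kymograph.
#' Among multiple candidate peaks in a column, the one nearest the
#' previous frame's position is chosen (the first frame uses the global
#' maximum).  Columns within `bead_exclusion_radii` bead radii of the
#' bead center are excluded; frames in which over half the columns fail
#' are flagged with a warning.
#'
#' @param stack A (preprocessed) `frame_stack`.
#' @param window Parabola window in px, as in [fit_deflection()].
#' @param bead_exclusion_radii Exclusion radius around the bead center in
#'   units of the bead radius.
#' @param bead_x Bead center x in m; taken from the stack metadata when
#'   present.
#' @return A [kymograph()]; `y` holds absolute positions in m.
#' @export
track_contour <- function(stack, window = 5L, bead_exclusion_radii = 2,
                          bead_x = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  nt <- d[3]; nc <- d[2]
  px <- stack$config$pixel_size
  x <- (seq_len(nc) - 1) * px
  if (is.null(bead_x)) bead_x <- stack$x_drive
  excluded <- if (!is.null(bead_x)) {
    which(abs(x - bead_x) <= bead_exclusion_radii * stack$config$bead_radius)
  } else integer(0)

  # background and noise floor are time-invariant (bleaching dims the
  # signal, not the background): estimate once from a reference frame
  ref <- stack$frames[, , 1]
  bg <- apply(ref, 2, stats::median)
  nz <- apply(ref, 2, stats::mad)

  centers <- matrix(NA_real_, nt, nc)
  quality <- matrix(NA_real_, nt, nc)
  valid <- matrix(FALSE, nt, nc)
  prev <- rep(NA_real_, nc)
  bad_frames <- 0L
  for (k in seq_len(nt)) {
    r <- fit_columns(stack$frames[, , k], window = window, prev = prev,
                     background = bg, noise = nz)
    centers[k, ] <- r$center
    quality[k, ] <- ifelse(r$valid, r$quality, NA_real_)
    valid[k, ] <- r$valid
    prev <- ifelse(r$valid, r$center, prev)
    if (mean(r$valid[setdiff(seq_len(nc), excluded)]) < 0.5)
      bad_frames <- bad_frames + 1L
  }
  if (bad_frames > 0)
    warning(sprintf("%d frame(s) had > 50%% failed columns", bad_frames))

  offset <- stack$row_offset_px %||% 0L
  kymograph(y = (centers + offset) * px, x = x, times = stack$times,
            quality = ifelse(valid, quality, 0), valid = valid,
            excluded_cols = excluded, pixel_size = px,
            drive = stack$drive)
}
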