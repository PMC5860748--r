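# Persistence: 16-bit multi-page grayscale TIFF for frames, a JSON
# sidecar for all metadata (imaging config, drive, rod, times), and a CSV
# export of the truth kymograph.  Counts are integers <= 65535, so the
# TIFF round trip is lossless.

#' Write a frame stack to disk
#'
#' Writes `<basename>.tif` (16-bit multi-page TIFF), `<basename>.json`
#' (imaging config, drive protocol, rod parameters, frame times) and,
#' when ground truth is attached, `<basename>_truth.csv` (long-format
#' kymograph).
#'
#' @param stack A `frame_stack`.
#' @param basename Output path without extension.
#' @return `basename`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, basename) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- dim(stack$frames)[3]
  pages <- lapply(seq_len(nt), function(k) stack$frames[, , k] / 65535)
  tiff::writeTIFF(pages, paste0(basename, ".tif"),
                  bits.per.sample = 16L, compression = "none")
  meta <- list(
    format = "bundlerheo-stack", version = 1L,
    config = unclass(stack$config),
    drive = unclass(stack$drive),
    rod = if (!is.null(stack$rod)) unclass(stack$rod) else NULL,
    times = stack$times,
    x_drive = stack$x_drive,
    l_omega_true = stack$l_omega_true,
    row_offset_px = stack$row_offset_px %||% 0L)
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(stack$truth))
    write_kymograph(stack$truth, paste0(basename, "_truth.csv"))
  invisible(basename)
}

#' Read a frame stack written by [write_stack()]
#'
#' Restores frames, metadata and (when present) the truth kymograph.
#' Malformed or truncated files raise an error naming the failing
#' component.
#'
#' @param basename Path without extension, as passed to [write_stack()].
#' @return A `frame_stack`.
#' @export
read_stack <- function(basename) {
  tif <- paste0(basename, ".tif")
  js <- paste0(basename, ".json")
  if (!file.exists(tif)) stop("missing TIFF file: ", tif)
  if (!file.exists(js)) stop("missing metadata sidecar: ", js)
  pages <- tryCatch(suppressWarnings(tiff::readTIFF(tif, all = TRUE)),
                    error = function(e) stop(
                      "unreadable TIFF '", tif, "': ", conditionMessage(e)))
  meta <- tryCatch(jsonlite::read_json(js, simplifyVector = TRUE),
                   error = function(e) stop(
                     "unreadable metadata '", js, "': ", conditionMessage(e)))
  if (!identical(meta$format, "bundlerheo-stack"))
    stop("'", js, "' is not a bundlerheo stack sidecar")
  nt <- length(pages)
  if (nt != length(meta$times))
    stop("TIFF holds ", nt, " frame(s) but metadata lists ",
         length(meta$times), "; file truncated after frame ", nt)
  frames <- array(0, dim = c(dim(pages[[1]]), nt))
  for (k in seq_len(nt)) {
    pg <- pages[[k]]
    if (!identical(dim(pg), dim(pages[[1]])))
      stop("frame ", k, " has inconsistent dimensions")
    frames[, , k] <- round(pg * 65535)
  }
  cfg <- meta$config; class(cfg) <- "imaging_config"
  drv <- meta$drive; class(drv) <- "drive_protocol"
  rod <- NULL
  if (!is.null(meta$rod) && length(meta$rod)) {
    rod <- meta$rod; class(rod) <- "rod_model"
  }
  truth <- NULL
  tcsv <- paste0(basename, "_truth.csv")
  if (file.exists(tcsv)) truth <- read_kymograph(tcsv, drive = drv)
  structure(list(frames = frames, times = as.numeric(meta$times),
                 config = cfg, drive = drv, rod = rod, truth = truth,
                 l_omega_true = meta$l_omega_true, x_drive = meta$x_drive,
                 row_offset_px = meta$row_offset_px),
            class = "frame_stack")
}

#' Write a kymograph as long-format CSV
#'
#' Columns: `time` (s), `x` (m), `y` (m, empty when untracked),
#' `quality`, `excluded`, `valid`.  A header comment row is avoided so
#' the file reads back with any CSV tool.
#'
#' @param kymo A [kymograph()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  df <- as.data.frame(kymo)
  df$pixel_size <- kymo$pixel_size
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path CSV path.
#' @param drive Optional [drive_protocol()] to attach as metadata.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path, drive = NULL) {
  df <- utils::read.csv(path)
  need <- c("time", "x", "y", "quality", "excluded", "valid")
  if (!all(need %in% names(df)))
    stop("'", path, "' lacks kymograph columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  times <- sort(unique(df$time))
  xs <- sort(unique(df$x))
  idx <- cbind(match(df$time, times), match(df$x, xs))
  y <- q <- matrix(NA_real_, length(times), length(xs))
  v <- matrix(FALSE, length(times), length(xs))
  y[idx] <- df$y; q[idx] <- df$quality; v[idx] <- df$valid
  q[!v] <- 0
  excl <- which(xs %in% unique(df$x[df$excluded]))
  kymograph(y = y, x = xs, times = times, quality = q, valid = v,
            excluded_cols = excl,
            pixel_size = if ("pixel_size" %in% names(df))
              df$pixel_size[1] else NA_real_,
            drive = drive)
}

#' Write an amplitude profile as CSV
#' @param profile An [bandpass()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "amplitude_profile"))
  df <- data.frame(x = profile$x, amplitude = profile$amplitude,
                   phase = profile$phase,
                   re = Re(profile$cvalue), im = Im(profile$cvalue))
  df$omega <- profile$omega
  df$n_periods_used <- profile$n_periods_used
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an amplitude profile written by [write_profile()]
#' @param path CSV path.
#' @param drive_point Optional drive point to attach.
#' @return An `amplitude_profile`.
#' @export
read_profile <- function(path, drive_point = NULL) {
  df <- utils::read.csv(path)
  structure(list(
    x = df$x, amplitude = df$amplitude, phase = df$phase,
    cvalue = complex(real = df$re, imaginary = df$im),
    n_periods_used = df$n_periods_used[1],
    omega = df$omega[1], frequency_hz = df$omega[1] / (2 * pi),
    drive_point = drive_point
  ), class = "amplitude_profile")
}

#' Write a hydrodynamic-length fit as JSON
#' @param fit A `hydro_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hydro_fit"))
  out <- unclass(fit)
  out$covariance <- as.vector(out$covariance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a hydrodynamic-length fit written by [write_fit()]
#' @param path JSON path.
#' @return A `hydro_fit`.
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  np <- length(x$par_names)
  x$covariance <- matrix(as.numeric(x$covariance), np, np)
  x$flags <- as.character(x$flags %||% character(0))
  structure(x, class = "hydro_fit")
}
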