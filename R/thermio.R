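#' Camera calibration description
#'
#' Linear two-point calibration mapping digital numbers to temperature,
#' `T = offset + scale * DN`, together with the configured measurement range
#' and emissivity. Defaults mirror a long-wave camera set up for exercise
#' thermography: emissivity 0.98, range 25-35 deg C.
#'
#' @param emissivity surface emissivity in (0, 1].
#' @param range_low,range_high configured measurement range in deg C.
#' @param scale deg C per digital number (default 0.001).
#' @param offset deg C at DN = 0 (default 25).
#' @return object of class `thermorun_calibration`.
#' @export
calibration_info <- function(emissivity = 0.98, range_low = 25, range_high = 35,
                             scale = 0.001, offset = 25) {
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  if (range_low >= range_high) stop("range_low must be below range_high")
  if (scale == 0) stop("scale must be non-zero")
  structure(list(emissivity = emissivity, range_low = range_low,
                 range_high = range_high, scale = scale, offset = offset),
            class = "thermorun_calibration")
}

#' Construct a radiometric frame
#'
#' One calibrated 2-D temperature field with acquisition metadata. The
#' fraction of pixels outside the configured measurement range is recorded as
#' a quality flag; out-of-range pixels are kept, never clamped, so that
#' histogram statistics remain unbiased.
#'
#' @param temperatures numeric matrix of temperatures in deg C (finite).
#' @param timestamp seconds from session start (>= 0).
#' @param frame_index integer frame number.
#' @param calibration a [calibration_info()] object.
#' @return object of class `thermorun_frame`: list with `temperatures`,
#'   `timestamp`, `frame_index`, `calibration`, `out_of_range_fraction`.
#' @export
radiometric_frame <- function(temperatures, timestamp = 0, frame_index = 0L,
                              calibration = calibration_info()) {
  temperatures <- as.matrix(temperatures)
  if (!all(is.finite(temperatures))) stop("temperatures must be finite")
  if (timestamp < 0) stop("timestamp must be >= 0")
  oor <- mean(temperatures < calibration$range_low |
                temperatures > calibration$range_high)
  structure(list(temperatures = temperatures, timestamp = timestamp,
                 frame_index = as.integer(frame_index),
                 calibration = calibration, out_of_range_fraction = oor),
            class = "thermorun_frame")
}

#' @export
print.thermorun_frame <- function(x, ...) {
  cat(sprintf("radiometric frame #%d @ %.3f s: %dx%d px, %.2f-%.2f degC, %.1f%% out of range\n",
              x$frame_index, x$timestamp, nrow(x$temperatures),
              ncol(x$temperatures), min(x$temperatures), max(x$temperatures),
              100 * x$out_of_range_fraction))
  invisible(x)
}

#' Construct a frame sequence
#'
#' @param frames list of [radiometric_frame()] objects with strictly
#'   increasing, uniformly spaced timestamps.
#' @param fps frame rate in Hz.
#' @param metadata free-form acquisition descriptors.
#' @return object of class `thermorun_sequence`.
#' @export
frame_sequence <- function(frames, fps, metadata = list()) {
  if (length(frames) == 0L) stop("empty frame list")
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (length(ts) > 1L) {
    d <- diff(ts)
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (max(d) - min(d) > 1e-6) stop("timestamps must be uniformly spaced")
  }
  structure(list(frames = frames, fps = fps, metadata = metadata),
            class = "thermorun_sequence")
}

#' @export
print.thermorun_sequence <- function(x, ...) {
  cat(sprintf("frame sequence: %d frames @ %.3g fps\n", length(x$frames), x$fps))
  invisible(x)
}

#' Apply a two-point calibration to raw digital numbers
#'
#' Elementwise linear map `T = offset + scale * DN`. Pixels falling outside
#' the configured measurement range are retained and counted in the frame's
#' `out_of_range_fraction`.
#'
#' @param raw_dn matrix of non-negative integer digital numbers.
#' @param cal a [calibration_info()] object.
#' @param timestamp,frame_index passed through to the frame.
#' @return a [radiometric_frame()].
#' @export
apply_two_point_calibration <- function(raw_dn, cal, timestamp = 0,
                                        frame_index = 0L) {
  raw_dn <- as.matrix(raw_dn)
  if (any(raw_dn < 0) || any(raw_dn != round(raw_dn))) {
    stop("raw_dn must be non-negative integers")
  }
  if (cal$scale == 0) stop("scale must be non-zero")
  radiometric_frame(cal$offset + cal$scale * raw_dn, timestamp, frame_index, cal)
}

#' Write a frame sequence to disk
#'
#' Stores the sequence as a multi-page 16-bit TIFF (`frames.tif`, digital
#' numbers under the sequence calibration) plus a JSON sidecar
#' (`sequence.json`) carrying fps, per-frame timestamps and the calibration,
#' defining an open on-disk equivalent of proprietary radiometric formats.
#' Temperatures round-trip to within half the calibration scale (the 16-bit
#' quantization step).
#'
#' @param seq a [frame_sequence()].
#' @param path directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "thermorun_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cal <- seq$frames[[1]]$calibration
  pages <- lapply(seq$frames, function(f) {
    dn <- round((f$temperatures - cal$offset) / cal$scale)
    dn <- pmin(pmax(dn, 0), 65535)
    dn / 65535
  })
  tiff::writeTIFF(pages, file.path(path, "frames.tif"), bits.per.sample = 16,
                  compression = "none")
  sidecar <- list(
    n_frames = length(seq$frames),
    fps = seq$fps,
    timestamps = vapply(seq$frames, function(f) f$timestamp, numeric(1)),
    frame_indices = vapply(seq$frames, function(f) f$frame_index, integer(1)),
    height = nrow(seq$frames[[1]]$temperatures),
    width = ncol(seq$frames[[1]]$temperatures),
    calibration = unclass(cal),
    metadata = seq$metadata)
  jsonlite::write_json(sidecar, file.path(path, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame sequence from disk
#'
#' Counterpart of [write_sequence()]: reads `frames.tif` and its
#' `sequence.json` sidecar and reconstructs temperatures via the stored
#' calibration. Errors on a missing sidecar ("no sequence found"), on a
#' frame/sidecar count mismatch, and on non-monotone timestamps.
#'
#' @param path directory containing `frames.tif` and `sequence.json`.
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path) {
  sidecar_path <- file.path(path, "sequence.json")
  tif_path <- file.path(path, "frames.tif")
  if (!file.exists(sidecar_path) || !file.exists(tif_path)) {
    stop("no sequence found in ", path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != sc$n_frames) {
    stop("frame/sidecar count mismatch: stack has ", length(pages),
         " frames, sidecar lists ", sc$n_frames)
  }
  if (any(diff(sc$timestamps) <= 0)) stop("non-monotone timestamps in sidecar")
  cal <- do.call(calibration_info, sc$calibration[c("emissivity", "range_low",
                                                   "range_high", "scale",
                                                   "offset")])
  frames <- lapply(seq_along(pages), function(i) {
    dn <- round(pages[[i]] * 65535)
    radiometric_frame(cal$offset + cal$scale * dn, sc$timestamps[i],
                      sc$frame_indices[i], cal)
  })
  frame_sequence(frames, sc$fps, as.list(sc$metadata))
}

#' Write a label-mask stack
#'
#' Masks are written as 8-bit PNG files (`mask_00001.png`, ...) with the
#' label palette {0 background, 1 non-vessel calf, 2 vein, 3 perforator}.
#'
#' @param masks list of integer label matrices.
#' @param path directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(masks, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!all(m %in% 0:3)) stop("mask labels must be in {0, 1, 2, 3}")
    png::writePNG(m / 255, file.path(path, sprintf("mask_%05d.png", i)))
  }
  invisible(path)
}

#' Read a label-mask stack written by [write_mask_stack()]
#'
#' @param path directory containing `mask_*.png` files.
#' @return list of integer label matrices.
#' @export
read_mask_stack <- function(path) {
  files <- sort(list.files(path, pattern = "^mask_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no mask stack found in ", path)
  lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "double"
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
}
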