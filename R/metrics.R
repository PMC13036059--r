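#' Compute the four skin-temperature metrics for one frame
#'
#' From a calibrated frame and a 4-label mask, computes the mean surface
#' radiation temperature over the whole calf (T_MEAN, labels {1,2,3}), the
#' non-vessel temperature (T_NV, label 1), the vein temperature (T_V, label
#' 2) and the perforator temperature (T_P, label 3), each with the Shannon
#' entropy (bits) of its pixel temperatures over a fixed histogram: bins of
#' `bin_width` deg C spanning the calibration range plus two open-ended
#' overflow bins. Regions with fewer than `min_pixels` pixels yield NA
#' temperature and entropy (downstream fusion interpolates these gaps).
#'
#' @param frame a [radiometric_frame()] or temperature matrix.
#' @param mask integer label matrix {0, 1, 2, 3}, same shape as the frame.
#' @param bin_width histogram bin width in deg C (default 0.1).
#' @param min_pixels minimum region size (default 25).
#' @param range_low,range_high histogram span in deg C; defaults come from
#'   the frame's calibration (25-35 for a plain matrix).
#' @param timestamp timestamp attached to the sample (default: frame's).
#' @return one-row data frame: `timestamp`, `t_mean`, `t_nv`, `t_v`, `t_p`,
#'   `h_mean`, `h_nv`, `h_v`, `h_p`, `n_mean`, `n_nv`, `n_v`, `n_p`.
#' @export
compute_tsk_sample <- function(frame, mask, bin_width = 0.1, min_pixels = 25,
                               range_low = NULL, range_high = NULL,
                               timestamp = NULL) {
  temps <- frame_temps(frame)
  if (!all(dim(temps) == dim(mask))) stop("mask shape does not match frame")
  if (inherits(frame, "thermorun_frame")) {
    if (is.null(range_low)) range_low <- frame$calibration$range_low
    if (is.null(range_high)) range_high <- frame$calibration$range_high
    if (is.null(timestamp)) timestamp <- frame$timestamp
  }
  if (is.null(range_low)) range_low <- 25
  if (is.null(range_high)) range_high <- 35
  if (is.null(timestamp)) timestamp <- NA_real_
  region <- function(sel) {
    v <- temps[sel]
    n <- length(v)
    if (n < min_pixels) {
      return(list(mean = NA_real_, h = NA_real_, n = n))
    }
    list(mean = mean(v),
         h = shannon_entropy(v, bin_width, range_low, range_high), n = n)
  }
  r_mean <- region(mask >= 1L)
  r_nv <- region(mask == 1L)
  r_v <- region(mask == 2L)
  r_p <- region(mask == 3L)
  data.frame(timestamp = timestamp,
             t_mean = r_mean$mean, t_nv = r_nv$mean, t_v = r_v$mean,
             t_p = r_p$mean,
             h_mean = r_mean$h, h_nv = r_nv$h, h_v = r_v$h, h_p = r_p$h,
             n_mean = r_mean$n, n_nv = r_nv$n, n_v = r_v$n, n_p = r_p$n)
}

#' Shannon entropy of pixel temperatures
#'
#' `H = -sum p_i log2 p_i` over a fixed histogram with bins of `bin_width`
#' spanning `[range_low, range_high]` plus two open-ended overflow bins.
#' Zero iff all pixels fall into one bin.
#'
#' @param values numeric pixel temperatures.
#' @param bin_width bin width (same units as values).
#' @param range_low,range_high histogram span.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(values, bin_width = 0.1, range_low = 25,
                            range_high = 35) {
  nbins <- ceiling((range_high - range_low) / bin_width)
  idx <- floor((values - range_low) / bin_width + 1e-9)
  idx[idx < 0] <- -1L       # low overflow bin
  idx[idx >= nbins] <- nbins  # high overflow bin
  counts <- tabulate(as.integer(idx) + 2L, nbins = nbins + 2L)
  p <- counts[counts > 0] / length(values)
  -sum(p * log2(p))
}

#' Metric time series over selected frames
#'
#' Applies [compute_tsk_sample()] to each selected frame of a sequence,
#' returning one row per selected frame ordered by timestamp. An empty
#' selection yields an empty table.
#'
#' @param seq a [frame_sequence()].
#' @param masks list of label matrices, parallel to `seq$frames`.
#' @param selected integer frame indices (1-based).
#' @param ... passed to [compute_tsk_sample()].
#' @return data frame of T_SK samples.
#' @export
metric_timeseries <- function(seq, masks, selected, ...) {
  stopifnot(inherits(seq, "thermorun_sequence"))
  if (length(selected) == 0L) {
    out <- compute_tsk_sample(matrix(30, 6, 6), matrix(1L, 6, 6))[0, ]
    return(out)
  }
  if (any(selected < 1L | selected > length(seq$frames))) {
    stop("selected index out of range")
  }
  rows <- lapply(selected, function(i) {
    compute_tsk_sample(seq$frames[[i]], masks[[i]], ...)
  })
  out <- do.call(rbind, rows)
  out[order(out$timestamp), , drop = FALSE]
}
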