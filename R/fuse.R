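#' Resample a sensor trace onto a target timeline
#'
#' Linear interpolation of a low-frequency sensor series onto the (usually
#' higher-frequency) thermography timeline; values outside the trace span are
#' held at the nearest endpoint.
#'
#' @param trace_times,trace_values source series (times strictly increasing,
#'   at least 2 points).
#' @param target_times times to evaluate at.
#' @return numeric vector on the target timeline.
#' @export
resample_to_timeline <- function(trace_times, trace_values, target_times) {
  keep <- is.finite(trace_times) & !is.na(trace_values)
  trace_times <- trace_times[keep]; trace_values <- trace_values[keep]
  if (length(trace_times) < 2L) stop("need at least 2 trace points")
  if (any(diff(trace_times) <= 0)) stop("trace times must be strictly increasing")
  stats::approx(trace_times, trace_values, xout = target_times, rule = 2)$y
}

#' Fill missing values in a series
#'
#' Interior gaps are filled by linear interpolation over the sample index;
#' leading and trailing gaps take the nearest defined value.
#'
#' @param x numeric vector, possibly with NAs.
#' @return vector of the same length with gaps filled (all-NA input is
#'   returned unchanged).
#' @export
interpolate_missing <- function(x) {
  idx <- which(is.finite(x))
  if (length(idx) == 0L) return(x)
  if (length(idx) == 1L) return(rep(x[idx], length(x)))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; exact on polynomials up to
#' `polyorder`, length-preserving.
#'
#' @param x numeric series.
#' @param window odd window length in samples (default 151).
#' @param polyorder polynomial order (default 3).
#' @return smoothed series of the same length.
#' @export
savgol_smooth <- function(x, window = 151, polyorder = 3) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(x)) stop("window longer than series")
  signal::sgolayfilt(x, p = polyorder, n = window)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Digital Butterworth low-pass with normalized cutoff (fraction of the
#' Nyquist frequency), applied forward-backward for zero phase by default.
#' Edge transients are controlled by odd-extension padding and steady-state
#' filter initialisation, so the filter has unit DC gain in practice
#' (constants pass through unchanged).
#'
#' @param x numeric series.
#' @param order filter order (default 3).
#' @param cutoff_normalized cutoff as a fraction of Nyquist, in (0, 1)
#'   (default 0.04).
#' @param zero_phase apply forward-backward (default TRUE); FALSE gives a
#'   single causal pass.
#' @return filtered series of the same length.
#' @export
butterworth_lowpass <- function(x, order = 3, cutoff_normalized = 0.04,
                                zero_phase = TRUE) {
  if (!is.numeric(cutoff_normalized) || cutoff_normalized <= 0 ||
      cutoff_normalized >= 1) {
    stop("cutoff_normalized must be in (0, 1)")
  }
  bf <- signal::butter(order, cutoff_normalized, type = "low")
  b <- bf$b; a <- bf$a
  n <- length(x)
  padlen <- min(n - 1L, max(3L * (length(a) - 1L), ceiling(3 / cutoff_normalized)))
  if (padlen < 1L) stop("series too short for the requested filter")
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- lfilter_ss(b, a, ext)
  if (zero_phase) {
    y <- rev(lfilter_ss(b, a, rev(y)))
  }
  y[(padlen + 1L):(padlen + n)]
}

# Direct-form-II-transposed IIR filter with steady-state initial conditions
# scaled to the first sample (suppresses the start-up transient).
lfilter_ss <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  # steady-state state vector for a unit step input
  if (nfilt > 1L) {
    A <- rbind(-a[2:nfilt], cbind(diag(nfilt - 2L), 0))
    if (nfilt == 2L) A <- matrix(-a[2], 1, 1)
    B <- b[2:nfilt] - a[2:nfilt] * b[1]
    zi <- solve(diag(nfilt - 1L) - t(A), B)
  } else {
    zi <- numeric(0)
  }
  # direct-form II transposed recursion with explicit initial state
  y <- numeric(length(x))
  z <- zi * x[1]
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + if (nfilt > 1L) z[1] else 0
    if (nfilt > 2L) {
      z[1:(nfilt - 2L)] <- b[2:(nfilt - 1L)] * xi + z[2:(nfilt - 1L)] -
        a[2:(nfilt - 1L)] * yi
      z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    } else if (nfilt == 2L) {
      z[1] <- b[2] * xi - a[2] * yi
    }
    y[i] <- yi
  }
  y
}

#' Centered rolling median
#'
#' Rolling median with a centered window; at the edges the window is
#' truncated to the available samples. NAs are ignored within a window.
#'
#' @param x numeric series.
#' @param window window width in samples (default 350). Even widths take
#'   `floor((window-1)/2)` samples to the left and the remainder to the
#'   right.
#' @return series of rolling medians, same length as `x`.
#' @export
rolling_median <- function(x, window = 350) {
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - left):min(n, i + right)]
    w <- w[is.finite(w)]
    if (length(w) == 0L) NA_real_ else stats::median(w)
  }, numeric(1))
}

#' Label protocol phases and treadmill ramp exclusions
#'
#' Derives the four analysis phases — warm-up (WU), first half (FH), second
#' half (SH) of the 36-min main block, and recovery (REC) — together with the
#' treadmill acceleration/deceleration intervals to exclude around every
#' commanded velocity change. The ramp model is a constant belt acceleration
#' (`ramp_rate` km/h per s) plus a safety margin.
#'
#' @param protocol a [build_protocol()] object.
#' @param ramp_rate treadmill acceleration in (km/h)/s (default 1).
#' @param margin extra seconds excluded after each ramp (default 2).
#' @return list with `phases` (data frame: phase, start, end) and
#'   `exclusions` (data frame: time of change, start, end).
#' @export
label_phases <- function(protocol, ramp_rate = 1, margin = 2) {
  stopifnot(inherits(protocol, "thermorun_protocol"))
  phases <- data.frame(
    phase = c("WU", "FH", "SH", "REC"),
    start = c(0, 600, 1680, 2760),
    end = c(600, 1680, 2760, protocol$total_duration),
    stringsAsFactors = FALSE)
  ph <- protocol$phases
  v <- c(0, ph$velocity)  # treadmill starts from standstill
  t_change <- ph$start
  dv <- abs(diff(v))
  keep <- dv > 0
  exclusions <- data.frame(
    time = t_change[keep],
    start = t_change[keep],
    end = t_change[keep] + dv[keep] / ramp_rate + margin)
  list(phases = phases, exclusions = exclusions)
}

#' Per-stage aggregation over the final seconds
#'
#' Represents each constant-velocity stage of the protocol by the mean of a
#' series over the stage's final `window` seconds, excluding samples inside
#' treadmill ramp intervals. A stage is flagged invalid when fewer than half
#' of the window samples are usable.
#'
#' @param time,value series on a common timeline (seconds).
#' @param protocol a [build_protocol()] object.
#' @param window aggregation window in seconds (default 5).
#' @param ramp_rate,margin passed to [label_phases()].
#' @return data frame with one row per stage: `stage`, `phase`, `mode`,
#'   `load_pct_viat`, `start`, `end`, `mean`, `n_used`, `valid`.
#' @export
aggregate_stage <- function(time, value, protocol, window = 5,
                            ramp_rate = 1, margin = 2) {
  lp <- label_phases(protocol, ramp_rate, margin)
  excl <- lp$exclusions
  ph <- protocol$phases
  in_ramp <- function(tt) {
    bad <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(excl))) {
      bad <- bad | (tt >= excl$start[i] & tt < excl$end[i])
    }
    bad
  }
  phase_of <- function(t_end) {
    i <- which(lp$phases$start < t_end & t_end <= lp$phases$end)
    if (length(i) == 0L) NA_character_ else lp$phases$phase[i[1]]
  }
  out <- lapply(seq_len(nrow(ph)), function(i) {
    t0 <- ph$end[i] - window; t1 <- ph$end[i]
    sel <- time > t0 & time <= t1
    n_window <- sum(sel)
    usable <- sel & !in_ramp(time) & is.finite(value)
    m <- if (any(usable)) mean(value[usable]) else NA_real_
    data.frame(stage = ph$name[i], phase = phase_of(ph$end[i]),
               mode = ph$mode[i], load_pct_viat = ph$pct_viat[i],
               start = ph$start[i], end = ph$end[i], mean = m,
               n_used = sum(usable),
               valid = n_window > 0 && sum(usable) >= 0.5 * n_window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort median series
#'
#' Elementwise median across participants at each timepoint, ignoring
#' missing values; timepoints where every participant is missing stay NA.
#'
#' @param mat numeric matrix, rows = timepoints, columns = participants.
#' @return numeric vector of medians, one per row.
#' @export
cohort_median_series <- function(mat) {
  mat <- as.matrix(mat)
  apply(mat, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) NA_real_ else stats::median(r)
  })
}
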