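#' Select stance-phase frames by calf area
#'
#' The stance phase of each step shows the largest, least-blurred calf.
#' The frame timeline is partitioned into consecutive windows of one gait
#' cycle (`round(fps / step_frequency)` frames); within each window the
#' frame with maximal segmented calf area is selected (ties go to the
#' earlier frame). Selections whose area falls below `min_area_fraction`
#' times the running median of the selected areas are dropped as occluded.
#'
#' @param areas per-frame calf pixel counts.
#' @param fps frame rate in Hz.
#' @param step_frequency gait cycle frequency in Hz (default 2.8, a typical
#'   running cadence). Each window must contain at least one frame, i.e.
#'   `round(fps / step_frequency) >= 1`.
#' @param min_area_fraction occlusion rejection threshold in (0, 1]
#'   (default 0.5).
#' @param median_window window (in selections) of the running median used
#'   for occlusion rejection (default 15, truncated to an odd length).
#' @return integer vector of selected frame indices, strictly increasing.
#' @export
select_stance_frames <- function(areas, fps, step_frequency = 2.8,
                                 min_area_fraction = 0.5,
                                 median_window = 15) {
  n <- length(areas)
  if (n == 0L) stop("empty area sequence")
  wlen <- as.integer(round(fps / step_frequency))
  if (wlen < 1L) stop("window of length < 1: step_frequency too high for fps")
  starts <- as.integer(seq.int(1L, n, by = wlen))
  sel <- vapply(starts, function(s) {
    e <- min(s + wlen - 1L, n)
    s + which.max(areas[s:e]) - 1L  # which.max: first index on ties
  }, integer(1))
  a_sel <- areas[sel]
  k <- min(median_window, length(a_sel))
  if (k %% 2 == 0) k <- k - 1L
  med <- if (k >= 1L) stats::runmed(a_sel, k, endrule = "median") else a_sel
  keep <- a_sel >= min_area_fraction * med
  sel[keep]
}
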