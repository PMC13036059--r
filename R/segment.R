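#' Segmentation parameters
#'
#' Settings of the classical calf/vessel segmenter: body thresholding (Otsu
#' on the temperature histogram, or a fixed threshold in deg C),
#' morphological cleanup, multiscale ridge enhancement and the rules that
#' split vessel candidates into elongated veins versus compact perforators.
#'
#' @param body_threshold_mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold in deg C when `body_threshold_mode`
#'   is `"fixed"`.
#' @param opening_radius morphological opening radius, px.
#' @param min_body_area minimum connected-component area for a calf, px.
#' @param ridge_scales Gaussian scales of the Hessian ridge filter, px.
#' @param vessel_quantile within-body response quantile used as the vessel
#'   threshold, in (0, 1).
#' @param elongation_threshold major/minor axis ratio above which a vessel
#'   component is a vein (> 1).
#' @param perforator_area_range admissible perforator component area, px.
#' @param ridge_amplitude_ref reference ridge amplitude (deg C) of the
#'   squash mapping the raw ridge response onto [0, 1).
#' @return object of class `thermorun_segment_params`.
#' @export
segment_params <- function(body_threshold_mode = c("otsu", "fixed"),
                           fixed_threshold = NULL, opening_radius = 2,
                           min_body_area = 100, ridge_scales = c(1, 2, 3),
                           vessel_quantile = 0.75, elongation_threshold = 3,
                           perforator_area_range = c(10, 200),
                           ridge_amplitude_ref = 1.0) {
  body_threshold_mode <- match.arg(body_threshold_mode)
  if (vessel_quantile <= 0 || vessel_quantile >= 1) {
    stop("vessel_quantile must be in (0, 1)")
  }
  if (elongation_threshold <= 1) stop("elongation_threshold must exceed 1")
  structure(list(body_threshold_mode = body_threshold_mode,
                 fixed_threshold = fixed_threshold,
                 opening_radius = opening_radius,
                 min_body_area = min_body_area, ridge_scales = ridge_scales,
                 vessel_quantile = vessel_quantile,
                 elongation_threshold = elongation_threshold,
                 perforator_area_range = perforator_area_range,
                 ridge_amplitude_ref = ridge_amplitude_ref),
            class = "thermorun_segment_params")
}

frame_temps <- function(frame) {
  if (inherits(frame, "thermorun_frame")) frame$temperatures else as.matrix(frame)
}

#' Segment the calf region of a thermogram
#'
#' Thresholds the temperature field (Otsu or fixed), applies a morphological
#' opening and hole filling, and keeps the up-to-two largest connected
#' components with area at least `min_body_area` (the two calves).
#'
#' @param frame a [radiometric_frame()] or temperature matrix.
#' @param params a [segment_params()].
#' @return logical calf mask (attribute `n_components` gives the number of
#'   calves found).
#' @export
segment_body <- function(frame, params = segment_params()) {
  temps <- frame_temps(frame)
  if (params$body_threshold_mode == "fixed") {
    if (is.null(params$fixed_threshold)) stop("fixed mode needs fixed_threshold")
    thr <- params$fixed_threshold
  } else {
    rng <- range(temps)
    if (diff(rng) <= 0) stop("no calf found: uniform image")
    norm <- (temps - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * diff(rng)
  }
  bw <- matrix(as.numeric(temps > thr), nrow(temps), ncol(temps))
  if (params$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$opening_radius + 1, shape = "disc")
    bw <- as.matrix(EBImage::opening(bw, brush))
  }
  bw <- as.matrix(EBImage::fillHull(bw))
  lab <- as.matrix(EBImage::bwlabel(bw))
  if (max(lab) == 0) stop("no calf found")
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- order(areas, decreasing = TRUE)
  keep <- keep[seq_len(min(2L, length(keep)))]
  keep <- keep[areas[keep] >= params$min_body_area]
  if (length(keep) == 0L) stop("no calf found: components below min_body_area")
  mask <- matrix(lab %in% keep, nrow(temps), ncol(temps))
  attr(mask, "n_components") <- length(keep)
  mask
}

#' Multiscale ridge/blob enhancement of warm vessel structures
#'
#' Hessian-based enhancement of bright curvilinear and punctate structures:
#' at each Gaussian scale s the scale-normalized most-negative Hessian
#' eigenvalue `-s^2 * lambda_2` (bright ridges and blobs have lambda_2 < 0)
#' is computed, the per-pixel maximum over scales is taken, and the raw
#' response r (deg C) is mapped onto [0, 1) by the strictly monotone squash
#' `r / (r + ridge_amplitude_ref)`, so a structure-free frame stays near 0
#' instead of being renormalized to full scale. The response is zeroed
#' outside the body interior (the body mask eroded past the largest scale) so
#' the calf/background step edge does not respond.
#'
#' @param frame a [radiometric_frame()] or temperature matrix.
#' @param body_mask logical calf mask from [segment_body()].
#' @param params a [segment_params()].
#' @return response matrix in [0, 1], zero outside the body interior.
#' @export
enhance_vessels <- function(frame, body_mask, params = segment_params()) {
  temps <- frame_temps(frame)
  if (!any(body_mask)) stop("empty body mask")
  h <- nrow(temps); w <- ncol(temps)
  # neutralize the calf/ambient step so the body edge does not respond
  work <- temps
  work[!body_mask] <- stats::median(temps[body_mask])
  resp <- matrix(0, h, w)
  for (s in params$ridge_scales) {
    sm <- as.matrix(EBImage::gblur(work, sigma = s))
    dxx <- hessian_xx(sm); dyy <- hessian_yy(sm); dxy <- hessian_xy(sm)
    # eigenvalues of the 2x2 Hessian; lambda_lo is the more negative one
    tr2 <- (dxx + dyy) / 2
    disc <- sqrt(pmax(((dxx - dyy) / 2)^2 + dxy^2, 0))
    lambda_lo <- tr2 - disc
    r_s <- s^2 * pmax(-lambda_lo, 0)
    resp <- pmax(resp, r_s)
  }
  erode_r <- ceiling(max(params$ridge_scales)) + 1L
  interior <- as.matrix(EBImage::erode(
    matrix(as.numeric(body_mask), h, w),
    EBImage::makeBrush(2 * erode_r + 1, shape = "disc"))) > 0
  resp[!interior] <- 0
  resp / (resp + params$ridge_amplitude_ref)
}

hessian_xx <- function(m) {  # second derivative along columns (x = width)
  h <- nrow(m); w <- ncol(m)
  ml <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  mr <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  mr - 2 * m + ml
}

hessian_yy <- function(m) {  # second derivative along rows (y = height)
  h <- nrow(m)
  mu <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  md <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  md - 2 * m + mu
}

hessian_xy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- c(1, seq_len(h - 1)); dn <- c(seq_len(h - 1) + 1, h)
  lf <- c(1, seq_len(w - 1)); rt <- c(seq_len(w - 1) + 1, w)
  (m[dn, rt, drop = FALSE] - m[dn, lf, drop = FALSE] -
     m[up, rt, drop = FALSE] + m[up, lf, drop = FALSE]) / 4
}

#' Classify vessel candidates into veins and perforators
#'
#' Thresholds the ridge response at the `vessel_quantile` of within-body
#' values, labels connected candidate components, and classifies each by
#' shape: elongation (major/minor axis ratio from second-order moments) at
#' least `elongation_threshold` makes a vein; otherwise an area inside
#' `perforator_area_range` makes a perforator; anything else is merged back
#' into non-vessel calf. Remaining body pixels are labelled 1.
#'
#' @param response output of [enhance_vessels()].
#' @param body_mask logical calf mask.
#' @param params a [segment_params()].
#' @return integer label matrix {0, 1, 2, 3} with attribute
#'   `source = "classical"`.
#' @export
classify_vessels <- function(response, body_mask, params = segment_params()) {
  h <- nrow(response); w <- ncol(response)
  labels <- matrix(0L, h, w)
  labels[body_mask] <- 1L
  vals <- response[body_mask]
  thr <- stats::quantile(vals, params$vessel_quantile, names = FALSE, type = 7)
  cand <- response > thr & body_mask
  if (any(cand)) {
    comp <- as.matrix(EBImage::bwlabel(matrix(as.numeric(cand), h, w)))
    for (k in seq_len(max(comp))) {
      px <- which(comp == k, arr.ind = TRUE)
      area <- nrow(px)
      el <- component_elongation(px)
      if (el >= params$elongation_threshold) {
        labels[px] <- 2L
      } else if (area >= params$perforator_area_range[1] &&
                 area <= params$perforator_area_range[2]) {
        labels[px] <- 3L
      }  # else stays 1 (non-vessel calf)
    }
  }
  attr(labels, "source") <- "classical"
  labels
}

# Major/minor axis ratio from the second-order central moments of a pixel
# set; 1/12 (the variance of a unit pixel) regularizes degenerate lines.
component_elongation <- function(px) {
  if (nrow(px) < 2L) return(1)
  cv <- stats::cov(px) * (nrow(px) - 1) / nrow(px)
  cv <- cv + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-12))
}

#' Full classical segmentation of one frame
#'
#' Convenience wrapper: [segment_body()], [enhance_vessels()],
#' [classify_vessels()].
#'
#' @inheritParams segment_body
#' @return integer label matrix {0, 1, 2, 3}.
#' @export
segment_frame <- function(frame, params = segment_params()) {
  body <- segment_body(frame, params)
  resp <- enhance_vessels(frame, body, params)
  classify_vessels(resp, body, params)
}

#' Oracle segmentation (ground-truth passthrough)
#'
#' Identity passthrough of a ground-truth mask, tagged with
#' `source = "oracle"`. Used to isolate downstream metric and fusion stages
#' from segmentation error.
#'
#' @param truth integer label matrix {0, 1, 2, 3}.
#' @return the same labels with attribute `source = "oracle"`.
#' @export
oracle_segment <- function(truth) {
  if (!all(truth %in% 0:3)) stop("mask labels must be in {0, 1, 2, 3}")
  out <- truth
  attr(out, "source") <- "oracle"
  out
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)`; returns 1 when both sets are empty.
#'
#' @param a,b logical masks of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
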