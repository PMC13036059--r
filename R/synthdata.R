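#' Synthetic thermogram scene configuration
#'
#' Geometry, thermal contrast and acquisition settings of the synthetic calf
#' thermogram generator: two elliptical calves on an ambient background, with
#' curvilinear superficial veins and punctate perforator vessels painted as
#' warm structures. Defaults are desk-scale (72 x 96 px at 2 fps with a
#' slowed 0.4 Hz gait so each gait cycle spans several frames); full camera
#' scale (768 x 1024 @ 30 fps, 2.8 Hz cadence) is supported by configuration.
#'
#' @param image_height,image_width frame size in pixels.
#' @param ambient_temp background (room) temperature, deg C.
#' @param base_skin_temp resting non-vessel skin temperature, deg C.
#' @param vein_delta,perforator_delta temperature offsets of vein and
#'   perforator pixels above non-vessel skin, deg C; must satisfy
#'   `vein_delta > perforator_delta > 0` so the metric ordering
#'   T_V > T_P > T_MEAN > T_NV holds at pixel level.
#' @param vein_count,perforator_count vessels per calf.
#' @param vessel_profile_sigma vessel cross-section half-width in pixels
#'   (veins are painted with a uniform top-hat profile of this half-width;
#'   perforators as discs of radius `1.5 * vessel_profile_sigma`).
#' @param noise_sigma i.i.d. Gaussian pixel noise, deg C (default 0.05).
#' @param fps frame rate in Hz.
#' @param gait_frequency gait cycle frequency in Hz.
#' @param swing_area_reduction fractional calf-area reduction at mid-swing
#'   (default 0.35).
#' @param swing_blur_sigma Gaussian motion-blur sigma for swing frames, px.
#' @param seed integer seed for the vessel layout.
#' @return object of class `thermorun_scene`.
#' @export
scene_config <- function(image_height = 72, image_width = 96,
                         ambient_temp = 20.2, base_skin_temp = 31.5,
                         vein_delta = 1.2, perforator_delta = 0.8,
                         vein_count = 2, perforator_count = 3,
                         vessel_profile_sigma = 1.5, noise_sigma = 0.05,
                         fps = 2, gait_frequency = 0.4,
                         swing_area_reduction = 0.35, swing_blur_sigma = 3,
                         seed = 1) {
  if (!(vein_delta > perforator_delta && perforator_delta > 0)) {
    stop("need vein_delta > perforator_delta > 0")
  }
  if (ambient_temp >= base_skin_temp) stop("ambient_temp must be below base_skin_temp")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (fps <= 0) stop("fps must be positive")
  structure(list(image_height = image_height, image_width = image_width,
                 ambient_temp = ambient_temp, base_skin_temp = base_skin_temp,
                 vein_delta = vein_delta, perforator_delta = perforator_delta,
                 vein_count = vein_count, perforator_count = perforator_count,
                 vessel_profile_sigma = vessel_profile_sigma,
                 noise_sigma = noise_sigma, fps = fps,
                 gait_frequency = gait_frequency,
                 swing_area_reduction = swing_area_reduction,
                 swing_blur_sigma = swing_blur_sigma, seed = seed),
            class = "thermorun_scene")
}

#' Physiological simulation parameters
#'
#' Parameters of the lumped first-order model that drives the synthetic
#' sensor traces and ground-truth skin-temperature series. Heart rate and
#' oxygen uptake follow first-order lags toward load-proportional targets;
#' core temperature is a saturating ramp driven by a low-pass-filtered
#' relative load (time constant `tau_load`, the thermal inertia of heat
#' production, which keeps the core rise continuous across short
#' intermittent bouts); non-vessel
#' skin temperature combines a fast sympathetic vasoconstriction state, a
#' slow heat-storage term proportional to the core-temperature rise, and a
#' post-exercise rebound state that activates when external load falls back
#' below `rebound_load_threshold` after running. Defaults are calibrated so
#' that, for the standard protocols, non-vessel skin temperature drops by
#' 1.1-1.3 deg C early in the warm-up and rebounds by about +1.4 deg C in the
#' first 3 min after a continuous session ends.
#'
#' @param hr_rest,hr_gain resting heart rate (bpm) and gain (bpm per % vIAT).
#' @param tau_hr,tau_vo2,tau_core,tau_fast,tau_rebound,tau_load time
#'   constants, s.
#' @param vo2_rest,vo2_gain resting VO2 (L/min) and gain (L/min per % vIAT).
#' @param tcore_baseline,tcore_rise core baseline (deg C) and steady-state
#'   rise at 85% vIAT (deg C).
#' @param tnv_baseline resting non-vessel skin temperature, deg C.
#' @param vasoconstriction_amp skin cooling at sustained 100% vIAT, deg C.
#' @param storage_gain deg C of skin warming per deg C of core rise.
#' @param rebound_amp,rebound_load_threshold post-exercise rebound amplitude
#'   (deg C) and the load (% vIAT) below which it activates.
#' @param vein_offset,perforator_offset vessel temperature offsets above
#'   non-vessel skin in the truth series, deg C.
#' @param hr_noise_sd,vo2_noise_sd,tcore_noise_sd additive Gaussian sensor
#'   noise standard deviations.
#' @param ant_bias constant offset of the heat-flux (ANT+) core channel
#'   relative to the ingestible pill, deg C.
#' @return object of class `thermorun_physio_params`.
#' @export
physio_params <- function(hr_rest = 62, hr_gain = 1.2, tau_hr = 30,
                          vo2_rest = 0.35, vo2_gain = 0.034, tau_vo2 = 40,
                          tcore_baseline = 37.0, tcore_rise = 1.1,
                          tau_core = 1200, tau_load = 600,
                          tnv_baseline = 31.5,
                          vasoconstriction_amp = 2.1, tau_fast = 45,
                          storage_gain = 2.8, rebound_amp = 0.35,
                          tau_rebound = 90, rebound_load_threshold = 40,
                          vein_offset = 1.2, perforator_offset = 0.8,
                          hr_noise_sd = 1, vo2_noise_sd = 0.04,
                          tcore_noise_sd = 0.01, ant_bias = 0.1) {
  if (any(c(tau_hr, tau_vo2, tau_core, tau_fast, tau_rebound, tau_load) <= 0)) {
    stop("all time constants must be positive")
  }
  if (!(vein_offset > perforator_offset && perforator_offset > 0)) {
    stop("need vein_offset > perforator_offset > 0")
  }
  p <- mget(names(formals(physio_params)))
  structure(p, class = "thermorun_physio_params")
}

#' Simulate sensor traces and ground-truth skin-temperature series
#'
#' Integrates the first-order physiological model over a running protocol
#' with exact exponential stepping (the load is piecewise constant over each
#' step, for which the first-order response has a closed form, so the
#' discrete series matches the continuous solution to machine precision),
#' preceded by a standing rest lead-in (negative times)
#' that provides the pre-exercise baseline. Returns the noisy sensor trace
#' (1/dt Hz) and the noise-free ground-truth skin-temperature metric series.
#'
#' @param protocol a [build_protocol()] object.
#' @param params a [physio_params()] object.
#' @param dt integration/sampling step in seconds (must be <= 1).
#' @param seed integer seed for sensor noise.
#' @param lead_in standing-rest lead-in duration before warm-up onset, s.
#' @param mean_weights named vector `c(f_v=, f_p=)`: nominal vein and
#'   perforator area fractions used for the ground-truth whole-calf mean.
#' @param noise add sensor noise (default TRUE).
#' @return object of class `thermorun_simulation`: list with `trace` (data
#'   frame: time, hr, vo2, tcore_pill, tcore_ant, rpe, ambient_temp,
#'   humidity, rer) and `truth` (data frame: time, t_nv, t_v, t_p, t_mean,
#'   tcore, load_pct).
#' @export
simulate_physiology <- function(protocol, params = physio_params(), dt = 1,
                                seed = 1, lead_in = 60,
                                mean_weights = c(f_v = 0.06, f_p = 0.02),
                                noise = TRUE) {
  stopifnot(inherits(protocol, "thermorun_protocol"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (dt > 1) stop("dt must be <= 1 s")
  if (nrow(protocol$phases) == 0L) stop("empty protocol")
  times <- seq(-lead_in, protocol$total_duration, by = dt)
  n <- length(times)
  u <- protocol_load(protocol, times)  # 0 before warm-up onset
  p <- params
  hr <- vo2 <- tcore <- xf <- xr <- numeric(n)
  hr[1] <- p$hr_rest; vo2[1] <- p$vo2_rest; tcore[1] <- p$tcore_baseline
  seen_high <- FALSE
  a_hr <- exp(-dt / p$tau_hr); a_vo2 <- exp(-dt / p$tau_vo2)
  a_core <- exp(-dt / p$tau_core); a_fast <- exp(-dt / p$tau_fast)
  a_reb <- exp(-dt / p$tau_rebound); a_load <- exp(-dt / p$tau_load)
  step <- function(x, target, a) target + (x - target) * a
  u_slow <- numeric(n)
  for (i in seq_len(n - 1L)) {
    ui <- u[i]
    if (ui >= 60) seen_high <- TRUE
    act <- as.numeric(seen_high && ui < p$rebound_load_threshold)
    hr[i + 1] <- step(hr[i], p$hr_rest + p$hr_gain * ui, a_hr)
    vo2[i + 1] <- step(vo2[i], p$vo2_rest + p$vo2_gain * ui, a_vo2)
    u_slow[i + 1] <- step(u_slow[i], ui, a_load)
    tcore[i + 1] <- step(tcore[i],
                         p$tcore_baseline + p$tcore_rise * u_slow[i + 1] / 85,
                         a_core)
    xf[i + 1] <- step(xf[i], ui / 100, a_fast)
    xr[i + 1] <- step(xr[i], act, a_reb)
  }
  t_nv <- p$tnv_baseline - p$vasoconstriction_amp * xf +
    p$storage_gain * (tcore - p$tcore_baseline) + p$rebound_amp * xr
  t_v <- t_nv + p$vein_offset
  t_p <- t_nv + p$perforator_offset
  fv <- mean_weights[["f_v"]]; fp <- mean_weights[["f_p"]]
  t_mean <- t_nv + fv * p$vein_offset + fp * p$perforator_offset
  truth <- data.frame(time = times, t_nv = t_nv, t_v = t_v, t_p = t_p,
                      t_mean = t_mean, tcore = tcore, load_pct = u)
  # sparse RPE at stage ends (Borg 6-20)
  rpe <- rep(NA_real_, n)
  stage_ends <- protocol$phases$end
  for (te in stage_ends) {
    j <- which.min(abs(times - te))
    rpe[j] <- min(20, max(6, round(6 + 0.13 * u[max(1L, j - 1L)])))
  }
  rer <- pmin(1.0, pmax(0.7, 0.75 + 0.25 * u / 105))
  trace <- local_rng(seed, {
    data.frame(
      time = times,
      hr = hr + if (noise) stats::rnorm(n, 0, p$hr_noise_sd) else 0,
      vo2 = pmax(0, vo2 + if (noise) stats::rnorm(n, 0, p$vo2_noise_sd) else 0),
      tcore_pill = tcore + if (noise) stats::rnorm(n, 0, p$tcore_noise_sd) else 0,
      tcore_ant = tcore + p$ant_bias +
        if (noise) stats::rnorm(n, 0, p$tcore_noise_sd) else 0,
      rpe = rpe,
      ambient_temp = 20.2 + if (noise) stats::rnorm(n, 0, 0.05) else 0,
      humidity = 44 + if (noise) stats::rnorm(n, 0, 0.3) else 0,
      rer = rer + if (noise) stats::rnorm(n, 0, 0.01) else 0)
  })
  structure(list(trace = trace, truth = truth, protocol = protocol,
                 params = params, dt = dt, seed = seed),
            class = "thermorun_simulation")
}

# --- scene geometry -------------------------------------------------------

# Phase-binned geometry of the two calves and their vessels. The gait cycle
# is discretized into `n_bins` phase bins; per bin the calf ellipses are
# scaled by the gait area profile and the vessel structures are re-rasterized
# in the scaled coordinates. Swing bins additionally carry Gaussian-blurred
# basis fields so full frames can be composed per frame with two AXPYs.
scene_geometry <- function(scene, seed = scene$seed, n_bins = 8L) {
  h <- scene$image_height; w <- scene$image_width
  sig <- scene$vessel_profile_sigma
  r_perf <- 1.5 * sig
  calves <- list(
    list(cy = h / 2, cx = w * 0.27, ar = 0.38 * h, ac = 0.16 * w),
    list(cy = h / 2, cx = w * 0.73, ar = 0.38 * h, ac = 0.16 * w))
  layout <- local_rng(seed, {
    lapply(calves, function(cf) {
      min_gap_u <- (r_perf + sig + 1) / cf$ac
      for (attempt in 1:30) {
        veins <- lapply(seq_len(scene$vein_count), function(k) {
          list(u0 = stats::runif(1, -0.55, 0.55),
               amp = stats::runif(1, 0.06, 0.18),
               freq = stats::runif(1, 0.8, 1.6),
               phase = stats::runif(1, 0, 2 * pi))
        })
        perfs <- list()
        tries <- 0L
        while (length(perfs) < scene$perforator_count && tries <= 300L) {
          tries <- tries + 1L
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * 0.68
          cand <- list(u = rad * cos(ang), v = rad * sin(ang))
          # keep painted discs from touching vein strokes / other perforators
          ok <- TRUE
          for (vn in veins) {
            ucl <- vn$u0 + vn$amp * sin(pi * vn$freq * cand$v + vn$phase)
            if (abs(cand$u - ucl) < min_gap_u) { ok <- FALSE; break }
          }
          if (ok) for (pf in perfs) {
            if ((cand$u - pf$u)^2 + (cand$v - pf$v)^2 < (3 * r_perf / cf$ac)^2) {
              ok <- FALSE; break
            }
          }
          if (ok) perfs[[length(perfs) + 1L]] <- cand
        }
        if (length(perfs) == scene$perforator_count) {
          return(list(calf = cf, veins = veins, perfs = perfs))
        }
      }
      stop("vessel counts exceed drawable area: could not place perforators")
    })
  })
  phi <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  swing_bin <- phi > pi / 2 & phi < 3 * pi / 2
  area_scale <- 1 - scene$swing_area_reduction * (1 - cos(phi)) / 2
  bins <- lapply(seq_len(n_bins), function(b) {
    g <- rasterize_scene(layout, h, w, area_scale[b], sig, r_perf)
    if (swing_bin[b]) {
      g$blur_body <- as.matrix(EBImage::gblur(
        matrix(as.numeric(g$labels > 0), h, w), sigma = scene$swing_blur_sigma))
      off <- scene$vein_delta * (g$labels == 2) +
        scene$perforator_delta * (g$labels == 3)
      g$blur_offset <- as.matrix(EBImage::gblur(off, sigma = scene$swing_blur_sigma))
    }
    g$swing <- swing_bin[b]
    g
  })
  list(bins = bins, phi = phi, n_bins = n_bins, layout = layout,
       swing_bin = swing_bin, area_scale = area_scale)
}

rasterize_scene <- function(layout, h, w, scale, sig, r_perf) {
  labels <- matrix(0L, h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  s <- sqrt(scale)
  for (side in layout) {
    cf <- side$calf
    ar <- cf$ar * s; ac <- cf$ac * s
    inside <- ((rr - cf$cy) / ar)^2 + ((cc - cf$cx) / ac)^2 <= 1
    labels[inside & labels == 0L] <- 1L
    paint_disc <- function(r0, c0, radius, value) {
      ri <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
      ci <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
      for (r in ri) for (cl in ci) {
        if ((r - r0)^2 + (cl - c0)^2 <= radius^2 && labels[r, cl] >= 1L) {
          labels[r, cl] <<- value
        }
      }
    }
    for (vn in side$veins) {
      vp <- seq(-0.82, 0.82, length.out = 160L)
      up <- vn$u0 + vn$amp * sin(pi * vn$freq * vp + vn$phase)
      rows <- cf$cy + vp * ar
      cols <- cf$cx + up * ac
      for (k in seq_along(vp)) paint_disc(rows[k], cols[k], sig, 2L)
    }
    for (pf in side$perfs) {
      r0 <- cf$cy + pf$v * ar
      c0 <- cf$cx + pf$u * ac
      ri <- max(1L, floor(r0 - r_perf)):min(h, ceiling(r0 + r_perf))
      ci <- max(1L, floor(c0 - r_perf)):min(w, ceiling(c0 + r_perf))
      for (r in ri) for (cl in ci) {
        if ((r - r0)^2 + (cl - c0)^2 <= r_perf^2 && labels[r, cl] == 1L) {
          labels[r, cl] <- 3L  # never overwrite a vein stroke
        }
      }
    }
  }
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L); n3 <- sum(labels == 3L)
  list(labels = labels, n_nv = n1, n_v = n2, n_p = n3, area = n1 + n2 + n3)
}

# Compose one frame from a geometry bin. Linear in t_nv, so blurred swing
# frames reuse precomputed blurred basis fields.
compose_frame <- function(scene, bin, t_nv, noise = TRUE) {
  if (isTRUE(bin$swing)) {
    temps <- scene$ambient_temp + (t_nv - scene$ambient_temp) * bin$blur_body +
      bin$blur_offset
  } else {
    temps <- scene$ambient_temp + (t_nv - scene$ambient_temp) * (bin$labels > 0) +
      scene$vein_delta * (bin$labels == 2L) +
      scene$perforator_delta * (bin$labels == 3L)
  }
  if (noise && scene$noise_sigma > 0) {
    temps <- temps + stats::rnorm(length(temps), 0, scene$noise_sigma)
    dim(temps) <- c(scene$image_height, scene$image_width)
  }
  temps
}

#' Render a single synthetic thermogram frame
#'
#' Draws two elliptical calves on the ambient background at the given
#' non-vessel skin temperature, with veins as curvilinear strokes (uniform
#' `vein_delta` offset over a top-hat cross-section) and perforators as
#' compact discs (`perforator_delta` offset). During the swing arc of the
#' gait cycle (phase in (pi/2, 3*pi/2)) the calf area is reduced and the
#' frame is motion-blurred. Mask labels {0 background, 1 calf, 2 vein,
#' 3 perforator} are consistent with the painted structures.
#'
#' @param scene a [scene_config()].
#' @param t_nv target non-vessel skin temperature for this frame, deg C.
#' @param gait_phase gait phase in radians.
#' @param seed optional integer seed for the pixel noise (default: current
#'   RNG state).
#' @param geometry optional precomputed geometry (from repeated calls);
#'   built from `scene$seed` when NULL.
#' @param timestamp,frame_index frame metadata.
#' @return list with `frame` (a [radiometric_frame()]), `mask` (label
#'   matrix), `is_swing` (logical).
#' @export
render_frame <- function(scene, t_nv, gait_phase = 0, seed = NULL,
                         geometry = NULL, timestamp = 0, frame_index = 0L) {
  if (is.null(geometry)) geometry <- scene_geometry(scene)
  b <- phase_bin(gait_phase, geometry$n_bins)
  bin <- geometry$bins[[b]]
  temps <- if (is.null(seed)) {
    compose_frame(scene, bin, t_nv)
  } else {
    local_rng(seed, compose_frame(scene, bin, t_nv))
  }
  list(frame = radiometric_frame(temps, timestamp, frame_index),
       mask = bin$labels, is_swing = bin$swing)
}

phase_bin <- function(phase, n_bins) {
  ph <- phase %% (2 * pi)
  1L + (floor(ph / (2 * pi / n_bins)) %% n_bins)
}

#' Generate a full synthetic running session
#'
#' End-to-end synthetic data for one participant and one running protocol:
#' physiological simulation (sensor traces at 1 Hz plus ground-truth metric
#' series), and a thermogram sequence with per-frame ground-truth masks at
#' `scene$fps / frame_stride` frames per second over the whole session.
#' Deterministic given `seed` (the physiology, vessel layout and pixel noise
#' use sub-seeds `seed`, `seed + 1`, `seed + 2`).
#'
#' @param session_id `"T1"`, `"T2"` or `"T3"`.
#' @param participant a row of [participants_reference()] or any list with a
#'   positive `viat_kmh` (or `viat`) element.
#' @param scene a [scene_config()].
#' @param params a [physio_params()]; its vessel offsets are overridden by
#'   the scene's `vein_delta`/`perforator_delta` so rendered frames and truth
#'   series agree.
#' @param seed integer seed.
#' @param frame_stride temporal downsampling stride (1 keeps `scene$fps`).
#' @param render render frames (default TRUE); FALSE keeps only sensors,
#'   truth series and protocol (fast, for cohort-scale reliability studies).
#' @return object of class `thermorun_session`: list with `frames`
#'   (a [frame_sequence()] or NULL), `truth_masks`, `truth_metrics` (data
#'   frame per frame: time, t_nv, t_v, t_p, t_mean, gait_phase, is_swing,
#'   area), `sensors`, `truth`, `protocol`, `participant`.
#' @export
generate_session <- function(session_id, participant, scene = scene_config(),
                             params = physio_params(), seed = 1,
                             frame_stride = 1, render = TRUE) {
  viat <- participant$viat_kmh
  if (is.null(viat)) viat <- participant$viat
  if (is.null(viat) || !is.finite(viat) || viat <= 0) {
    stop("participant must carry a positive vIAT")
  }
  seed <- as.integer(seed)
  params$vein_offset <- scene$vein_delta
  params$perforator_offset <- scene$perforator_delta
  protocol <- build_protocol(session_id, viat)
  geometry0 <- scene_geometry(scene, seed = seed + 1L)
  stance_bin <- geometry0$bins[[1L]]
  fw <- c(f_v = stance_bin$n_v / stance_bin$area,
          f_p = stance_bin$n_p / stance_bin$area)
  names(fw) <- c("f_v", "f_p")
  sim <- simulate_physiology(protocol, params, dt = 1, seed = seed,
                             mean_weights = fw)
  fps_eff <- scene$fps / frame_stride
  n_frames <- floor(protocol$total_duration * fps_eff)
  t_frames <- (seq_len(n_frames) - 1L) / fps_eff
  tru <- sim$truth
  tnv_frames <- stats::approx(tru$time, tru$t_nv, xout = t_frames, rule = 2)$y
  gait_phase <- (2 * pi * scene$gait_frequency * t_frames) %% (2 * pi)
  bins_idx <- phase_bin(gait_phase, geometry0$n_bins)
  bin_tab <- geometry0$bins
  frames <- NULL
  truth_masks <- NULL
  if (render) {
    cal <- calibration_info()
    frames_list <- local_rng(seed + 2L, {
      lapply(seq_len(n_frames), function(j) {
        temps <- compose_frame(scene, bin_tab[[bins_idx[j]]], tnv_frames[j])
        radiometric_frame(temps, t_frames[j], j - 1L, cal)
      })
    })
    frames <- frame_sequence(frames_list, fps_eff,
                             metadata = list(session_id = session_id,
                                             seed = seed,
                                             frame_stride = frame_stride))
    truth_masks <- lapply(bins_idx, function(b) bin_tab[[b]]$labels)
  }
  tm_mean <- vapply(bins_idx, function(b) {
    g <- bin_tab[[b]]
    (g$n_v * scene$vein_delta + g$n_p * scene$perforator_delta) / g$area
  }, numeric(1))
  truth_metrics <- data.frame(
    time = t_frames,
    t_nv = tnv_frames,
    t_v = tnv_frames + scene$vein_delta,
    t_p = tnv_frames + scene$perforator_delta,
    t_mean = tnv_frames + tm_mean,
    gait_phase = gait_phase,
    is_swing = geometry0$swing_bin[bins_idx],
    area = vapply(bins_idx, function(b) bin_tab[[b]]$area, numeric(1)))
  structure(list(frames = frames, truth_masks = truth_masks,
                 truth_metrics = truth_metrics, sensors = sim$trace,
                 truth = sim$truth, protocol = protocol,
                 participant = participant, scene = scene, params = params,
                 seed = seed, frame_stride = frame_stride,
                 geometry = geometry0),
            class = "thermorun_session")
}

#' @export
print.thermorun_session <- function(x, ...) {
  cat(sprintf("synthetic session %s: %s frames, %d sensor samples, seed %d\n",
              x$protocol$session_id,
              if (is.null(x$frames)) "no" else length(x$frames$frames),
              nrow(x$sensors), x$seed))
  invisible(x)
}
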