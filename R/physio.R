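#' Build a treadmill running protocol
#'
#' Constructs the load structure of one of the three standardized running
#' sessions. Every session consists of a 10-min warm-up at 60% of the running
#' velocity at the individual anaerobic threshold (vIAT), a 36-min main block,
#' and a 3-min walking recovery at a fixed 4 km/h; treadmill incline is 1.5%.
#' The main block is either fully continuous at 85% vIAT (`"T1"`), continuous
#' followed by intermittent (`"T2"`), or intermittent followed by continuous
#' (`"T3"`). The intermittent half consists of three sequences of 3 min at
#' 105% vIAT alternating with 3 min at 65% vIAT, so the mean relative load of
#' the main block is 85% vIAT in all three sessions.
#'
#' @param session_id one of `"T1"`, `"T2"`, `"T3"`.
#' @param viat running velocity at the individual anaerobic threshold, km/h.
#' @param incline treadmill incline in percent (default 1.5).
#' @return An object of class `thermorun_protocol`: a list with `session_id`,
#'   `incline`, `total_duration` (seconds) and `phases`, a data frame with one
#'   row per constant-velocity stage (`name`, `start`, `end`, `pct_viat`,
#'   `velocity`, `mode`).
#' @examples
#' p <- build_protocol("T2", viat = 12.2)
#' p$phases
#' @export
build_protocol <- function(session_id, viat, incline = 1.5) {
  if (!is.character(session_id) || length(session_id) != 1L ||
      !session_id %in% c("T1", "T2", "T3")) {
    stop("unknown session_id: must be one of 'T1', 'T2', 'T3'")
  }
  if (!is.numeric(viat) || length(viat) != 1L || !is.finite(viat) || viat <= 0) {
    stop("viat must be a positive finite number [km/h]")
  }
  wu <- data.frame(name = "WU", start = 0, end = 600, pct_viat = 60,
                   mode = "WU", stringsAsFactors = FALSE)
  con_block <- function(start, label) {
    data.frame(name = label, start = start, end = start + 1080,
               pct_viat = 85, mode = "CON", stringsAsFactors = FALSE)
  }
  int_block <- function(start) {
    pct <- rep(c(105, 65), 3L)
    s <- start + 180 * (0:5)
    data.frame(name = paste0("INT", 1:6), start = s, end = s + 180,
               pct_viat = pct, mode = "INT", stringsAsFactors = FALSE)
  }
  main <- switch(session_id,
    T1 = data.frame(name = "CON", start = 600, end = 2760, pct_viat = 85,
                    mode = "CON", stringsAsFactors = FALSE),
    T2 = rbind(con_block(600, "CON"), int_block(1680)),
    T3 = rbind(int_block(600), con_block(1680, "CON")))
  rec <- data.frame(name = "REC", start = 2760, end = 2940,
                    pct_viat = 100 * 4 / viat, mode = "WALK",
                    stringsAsFactors = FALSE)
  phases <- rbind(wu, main, rec)
  phases$velocity <- ifelse(phases$mode == "WALK", 4, phases$pct_viat / 100 * viat)
  rownames(phases) <- NULL
  structure(list(session_id = session_id, viat = viat, incline = incline,
                 total_duration = 2940, phases = phases),
            class = "thermorun_protocol")
}

#' @export
print.thermorun_protocol <- function(x, ...) {
  cat(sprintf("Running protocol %s (vIAT %.1f km/h, incline %.1f%%, %d min)\n",
              x$session_id, x$viat, x$incline, x$total_duration %/% 60))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Piecewise-constant relative load of a protocol
#'
#' Evaluates the commanded external load (% vIAT) at arbitrary times.
#' Times at a phase boundary take the load of the phase that starts there;
#' times outside `[0, total_duration]` return 0 (treadmill at rest).
#'
#' @param protocol a [build_protocol()] object.
#' @param times numeric vector of times in seconds.
#' @return numeric vector of loads in % vIAT.
#' @export
protocol_load <- function(protocol, times) {
  stopifnot(inherits(protocol, "thermorun_protocol"))
  ph <- protocol$phases
  out <- numeric(length(times))
  for (i in seq_len(nrow(ph))) {
    sel <- times >= ph$start[i] & times < ph$end[i]
    out[sel] <- ph$pct_viat[i]
  }
  out[times == protocol$total_duration] <- ph$pct_viat[nrow(ph)]
  out
}

#' Reference participant cohort
#'
#' Anthropometric and fitness characteristics of the 11-runner reference
#' cohort shipped with the package (id, sex, age, height, body mass, BMI,
#' body fat, lean mass, BSA, physical-activity rating, vIAT, relative
#' VO2max). Used for worked examples and as the participant pool of the
#' synthetic cohort generator.
#'
#' @return data frame with 11 rows.
#' @export
participants_reference <- function() {
  path <- system.file("extdata", "participants_reference.csv",
                      package = "thermorun", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Mosteller body surface area
#'
#' `BSA = sqrt(height_cm * mass_kg / 3600)` in square metres.
#'
#' @param height_cm body height in cm.
#' @param mass_kg body mass in kg.
#' @return BSA in m^2 (vectorized).
#' @examples bsa_mosteller(178, 76.3)
#' @export
bsa_mosteller <- function(height_cm, mass_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(mass_kg)) ||
      any(height_cm <= 0) || any(mass_kg <= 0)) {
    stop("height_cm and mass_kg must be positive and finite")
  }
  sqrt(height_cm * mass_kg / 3600)
}

#' Body mass index
#'
#' @param mass_kg body mass in kg.
#' @param height_cm body height in cm.
#' @return BMI in kg/m^2 (vectorized).
#' @export
bmi <- function(mass_kg, height_cm) {
  if (any(!is.finite(height_cm)) || any(!is.finite(mass_kg)) ||
      any(height_cm <= 0) || any(mass_kg <= 0)) {
    stop("mass_kg and height_cm must be positive and finite")
  }
  mass_kg / (height_cm / 100)^2
}

#' Metabolic rate from indirect calorimetry
#'
#' Converts oxygen uptake to metabolic power using RER-weighted energy
#' equivalents of carbohydrate (21.13 kJ/L O2) and fat (19.62 kJ/L O2):
#' `M = vo2/60 * 1000 * (((rer-0.7)/0.3)*21.13 + ((1-rer)/0.3)*19.62)` watts.
#' RER values outside the physiological steady-state range are clamped to
#' `[0.7, 1.0]` with a warning.
#'
#' @param vo2 oxygen uptake in L/min.
#' @param rer respiratory exchange ratio (dimensionless).
#' @return metabolic rate in W (vectorized).
#' @examples metabolic_rate(1.0, 1.0)  # 352.17 W
#' @export
metabolic_rate <- function(vo2, rer) {
  if (any(!is.finite(vo2)) || any(vo2 < 0)) stop("vo2 must be non-negative")
  if (any(rer < 0.7 | rer > 1.0)) {
    warning("RER outside [0.7, 1.0] clamped (non-steady-state breaths)")
    rer <- pmin(pmax(rer, 0.7), 1.0)
  }
  e_kj_per_l <- ((rer - 0.7) / 0.3) * 21.13 + ((1.0 - rer) / 0.3) * 19.62
  vo2 / 60 * 1000 * e_kj_per_l
}

#' External work rate on an inclined treadmill
#'
#' Vertical lifting power under the small-angle approximation:
#' `W = mass * g * v * grade` with `v` in m/s. Level running is treated as
#' zero external work.
#'
#' @param mass_kg body mass in kg.
#' @param velocity_kmh treadmill belt velocity in km/h.
#' @param grade incline as a fraction (1.5% -> 0.015).
#' @return external work rate in W.
#' @export
external_work_rate <- function(mass_kg, velocity_kmh, grade) {
  mass_kg * 9.81 * (velocity_kmh / 3.6) * grade
}

#' Metabolic heat production rate
#'
#' `MHP = (metabolic_rate - external_work) / BSA` in W/m^2, the net rate at
#' which metabolic energy is released as heat, normalized to body surface
#' area.
#'
#' @param metabolic_rate_w metabolic rate in W.
#' @param external_work_w external work rate in W.
#' @param bsa_m2 body surface area in m^2.
#' @return MHP in W/m^2.
#' @export
mhp <- function(metabolic_rate_w, external_work_w, bsa_m2) {
  if (any(!is.finite(bsa_m2)) || any(bsa_m2 <= 0)) stop("bsa_m2 must be > 0")
  (metabolic_rate_w - external_work_w) / bsa_m2
}

#' Sweat loss from pre/post body mass
#'
#' Difference in body mass before and after exercise, in grams. A negative
#' loss (mass gain) is returned as-is with attribute `flagged = TRUE`.
#'
#' @param mass_pre_kg,mass_post_kg body mass before/after exercise in kg.
#' @return sweat loss in g; attribute `flagged` marks negative values.
#' @export
sweat_loss <- function(mass_pre_kg, mass_post_kg) {
  out <- (mass_pre_kg - mass_post_kg) * 1000
  flag <- out < 0
  if (any(flag)) warning("negative sweat loss (mass gain) flagged")
  attr(out, "flagged") <- flag
  out
}

#' Core-to-skin temperature gradient
#'
#' @param tcore core temperature in deg C.
#' @param tnv non-vessel skin temperature in deg C.
#' @return gradient `tcore - tnv` in deg C.
#' @export
core_skin_gradient <- function(tcore, tnv) tcore - tnv

#' Individual anaerobic threshold (Dickhuth model)
#'
#' Determines the running velocity at the individual anaerobic threshold from
#' an incremental lactate-velocity test. The lactate equivalent
#' `l(v) = lactate / divisor(v)` (divisor is velocity by default, or VO2 when
#' supplied) is minimized over stages with parabolic refinement through the
#' three stages around the discrete minimum; the IAT is the velocity at which
#' the piecewise-linear lactate-velocity curve above the lactate-threshold
#' velocity reaches baseline lactate + 1.5 mmol/L.
#'
#' @param velocity stage velocities in km/h, strictly increasing.
#' @param lactate blood lactate per stage in mmol/L, positive.
#' @param vo2 optional per-stage VO2 (L/min); when given, the lactate
#'   equivalent uses lactate/VO2 instead of lactate/velocity.
#' @param delta lactate offset above the threshold value (default 1.5 mmol/L).
#' @return list with `viat` (km/h), `v_lt` (lactate-equivalent minimum
#'   velocity), `lactate_lt` (lactate at the minimum).
#' @export
iat_dickhuth <- function(velocity, lactate, vo2 = NULL, delta = 1.5) {
  n <- length(velocity)
  if (n < 4L) stop("need at least 4 stages")
  if (length(lactate) != n) stop("velocity and lactate lengths differ")
  if (any(diff(velocity) <= 0)) stop("velocities must be strictly increasing")
  if (any(lactate <= 0)) stop("lactate must be positive")
  divisor <- if (is.null(vo2)) velocity else vo2
  leq <- lactate / divisor
  i0 <- which.min(leq)
  # parabolic refinement around the discrete minimum (interior points only)
  v_lt <- velocity[i0]
  if (i0 > 1L && i0 < n) {
    vx <- velocity[(i0 - 1):(i0 + 1)]
    ly <- leq[(i0 - 1):(i0 + 1)]
    num <- (vx[2] - vx[1])^2 * (ly[2] - ly[3]) - (vx[2] - vx[3])^2 * (ly[2] - ly[1])
    den <- (vx[2] - vx[1]) * (ly[2] - ly[3]) - (vx[2] - vx[3]) * (ly[2] - ly[1])
    if (is.finite(den) && abs(den) > .Machine$double.eps) {
      v_ref <- vx[2] - 0.5 * num / den  # vertex of the interpolating parabola
      v_lt <- min(max(v_ref, vx[1]), vx[3])
    }
  }
  lac_lt <- stats::approx(velocity, lactate, xout = v_lt, rule = 2)$y
  target <- lac_lt + delta
  # walk the piecewise-linear lactate curve above v_lt for the first crossing
  vs <- c(v_lt, velocity[velocity > v_lt])
  ls <- c(lac_lt, lactate[velocity > v_lt])
  viat <- NA_real_
  for (j in seq_len(length(vs) - 1L)) {
    l0 <- ls[j]; l1 <- ls[j + 1L]
    if ((l0 <= target && l1 >= target) && l1 > l0) {
      viat <- vs[j] + (target - l0) / (l1 - l0) * (vs[j + 1L] - vs[j])
      break
    }
  }
  if (!is.finite(viat)) stop("IAT beyond test range: lactate never reaches threshold + ",
                             delta, " mmol/L")
  list(viat = viat, v_lt = v_lt, lactate_lt = lac_lt)
}

#' Phase-anchored delta metric
#'
#' Difference of a series between two protocol anchors, each evaluated as the
#' mean over the `window` seconds ending at the anchor (mirroring last-5-s
#' stage aggregation). Anchors may be given as times in seconds or as names
#' `"Pre"`, `"WU-end"`, `"FH-end"`, `"SH-end"`, `"REC-end"` resolved against a
#' protocol.
#'
#' @param time,value the series.
#' @param from,to anchors (numeric seconds or anchor names).
#' @param protocol optional [build_protocol()] object, required for named
#'   anchors.
#' @param window averaging window in seconds (default 5).
#' @return delta value `to - from`.
#' @export
delta_metric <- function(time, value, from, to, protocol = NULL, window = 5) {
  at <- function(anchor) {
    t_a <- resolve_anchor(anchor, protocol)
    sel <- time > t_a - window & time <= t_a
    if (!any(sel)) sel <- which.min(abs(time - t_a))
    mean(value[sel], na.rm = TRUE)
  }
  at(to) - at(from)
}

resolve_anchor <- function(anchor, protocol) {
  if (is.numeric(anchor)) return(anchor)
  if (is.null(protocol)) stop("named anchors need a protocol")
  switch(anchor,
    "Pre" = 0,  # warm-up onset; the baseline window is the 5 s before it
    "WU-end" = 600,
    "FH-end" = 1680,
    "SH-end" = 2760,
    "REC-end" = protocol$total_duration,
    stop("unknown anchor: ", anchor))
}
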