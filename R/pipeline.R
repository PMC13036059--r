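#' Participant-specific physiological parameters
#'
#' Derives per-participant simulation parameters from the cohort defaults:
#' a deterministic fitness link (stronger exercise-onset vasoconstriction
#' with higher vIAT, mirroring the observed association between submaximal
#' capacity and early skin-temperature drop) plus seeded inter-individual
#' jitter on baselines and amplitudes.
#'
#' @param params cohort-level [physio_params()].
#' @param participant list/row with `viat_kmh` (or `viat`).
#' @param seed integer seed for the jitter.
#' @param viat_ref reference vIAT (km/h) at which the fitness link is
#'   neutral (default 12.2, the cohort mean).
#' @param jitter_sd relative jitter standard deviation (default 0.06).
#' @return a modified `thermorun_physio_params` object.
#' @export
participant_params <- function(params, participant, seed = 1,
                               viat_ref = 12.2, jitter_sd = 0.06) {
  viat <- participant$viat_kmh
  if (is.null(viat)) viat <- participant$viat
  p <- params
  p$vasoconstriction_amp <- p$vasoconstriction_amp * (1 + 0.04 * (viat - viat_ref))
  local_rng(seed, {
    p$tnv_baseline <- p$tnv_baseline + stats::rnorm(1, 0, 0.3)
    p$vasoconstriction_amp <- p$vasoconstriction_amp * exp(stats::rnorm(1, 0, jitter_sd))
    p$storage_gain <- p$storage_gain * exp(stats::rnorm(1, 0, jitter_sd))
    p$hr_rest <- p$hr_rest + stats::rnorm(1, 0, 3)
    p$rebound_amp <- p$rebound_amp * exp(stats::rnorm(1, 0, jitter_sd))
  })
  p
}

default_run_config <- function() {
  list(session_id = "T1", participant = 1L, seed = 1L, frame_stride = 1L,
       scene = list(), physio = list(), segmentation = "oracle",
       external_masks = NULL, step_frequency = NULL, min_area_fraction = 0.5,
       bin_width = 0.1, min_pixels = 25, smoothing_seconds = 54,
       stage_window = 5, out_dir = NULL, write_frames = FALSE)
}

#' Run the full single-session analysis pipeline
#'
#' Orchestrates simulate -> segment -> select -> metrics -> fuse -> physio ->
#' report for one synthetic running session: generates the session, produces
#' masks (ground-truth oracle, classical segmenter, or an external mask
#' stack), selects stance-phase frames by calf area, computes the four T_SK
#' metrics with entropies, aligns the sensor traces to the selected-frame
#' timeline with Savitzky-Golay smoothing of the metric series, aggregates
#' stages (final-5-s means, treadmill ramps excluded) and phase deltas, and
#' derives participant-level physiology (BSA, BMI, end-exercise metabolic
#' heat production). Reruns with the same configuration are bit-identical.
#'
#' @param config named list (or path to a YAML file) overriding the
#'   defaults: `session_id`, `participant` (index into
#'   [participants_reference()] or a list with anthropometrics), `seed`,
#'   `frame_stride`, `scene` and `physio` (constructor overrides),
#'   `segmentation` ("oracle", "classical", "external"), `external_masks`
#'   (directory for "external"), `step_frequency` (defaults to the scene
#'   gait frequency), `min_area_fraction`, `bin_width`, `min_pixels`,
#'   `smoothing_seconds` (Savitzky-Golay window expressed in seconds of
#'   selected-frame time, default 54), `stage_window` (final-seconds
#'   aggregation window, default 5), `out_dir`, `write_frames`.
#' @return object of class `thermorun_run`: list with `session`, `masks`,
#'   `selected`, `tsk` (per-frame metrics), `synced` (synchronized table),
#'   `stages` (per-variable stage summaries), `deltas`, `derived`,
#'   `manifest`.
#' @export
run_session_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s stage failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  participant <- cfg$participant
  if (is.numeric(participant)) {
    participant <- as.list(participants_reference()[participant, ])
  }
  scene <- do.call(scene_config, cfg$scene)
  physio <- do.call(physio_params, cfg$physio)

  session <- stage("simulate", generate_session(
    cfg$session_id, participant, scene = scene, params = physio,
    seed = cfg$seed, frame_stride = cfg$frame_stride))
  fps_eff <- session$frames$fps

  masks <- stage("segment", switch(cfg$segmentation,
    oracle = lapply(session$truth_masks, oracle_segment),
    classical = lapply(session$frames$frames, segment_frame),
    external = {
      if (is.null(cfg$external_masks)) stop("external mode needs external_masks")
      lapply(read_mask_stack(cfg$external_masks), oracle_segment)
    },
    stop("unknown segmentation mode: ", cfg$segmentation)))

  selected <- stage("select", {
    areas <- vapply(masks, function(m) as.numeric(sum(m >= 1L)), numeric(1))
    step_freq <- if (is.null(cfg$step_frequency)) scene$gait_frequency else
      cfg$step_frequency
    select_stance_frames(areas, fps_eff, step_freq, cfg$min_area_fraction)
  })

  tsk <- stage("metrics", metric_timeseries(
    session$frames, masks, selected,
    bin_width = cfg$bin_width, min_pixels = cfg$min_pixels))

  synced <- stage("fuse", {
    tt <- tsk$timestamp
    rate <- 1 / stats::median(diff(tt))
    win <- max(5L, round(cfg$smoothing_seconds * rate))
    if (win %% 2 == 0) win <- win + 1L
    win <- min(win, length(tt) - (1 - length(tt) %% 2))
    if (win %% 2 == 0) win <- win - 1L
    smooth_col <- function(v) {
      v <- interpolate_missing(v)
      if (win > 3 && win <= length(v)) savgol_smooth(v, win, 3) else v
    }
    out <- data.frame(time = tt)
    for (cn in c("t_mean", "t_nv", "t_v", "t_p",
                 "h_mean", "h_nv", "h_v", "h_p")) {
      out[[cn]] <- smooth_col(tsk[[cn]])
    }
    sens <- session$sensors
    for (cn in c("hr", "vo2", "tcore_pill", "tcore_ant", "ambient_temp",
                 "humidity", "rer")) {
      out[[cn]] <- resample_to_timeline(sens$time, sens[[cn]], tt)
    }
    out
  })

  stages <- stage("physio", {
    vars <- c("t_nv", "t_p", "t_mean", "t_v", "hr", "vo2", "tcore_pill")
    do.call(rbind, lapply(vars, function(v) {
      st <- aggregate_stage(synced$time, synced[[v]], session$protocol,
                            window = cfg$stage_window)
      st$variable <- v
      st
    }))
  })

  deltas <- stage("physio", {
    anchors <- list(c("Pre", "WU-end"), c("WU-end", "FH-end"),
                    c("FH-end", "SH-end"), c("SH-end", "REC-end"),
                    c("Pre", "FH-end"))
    do.call(rbind, lapply(c("t_nv", "t_p"), function(v) {
      do.call(rbind, lapply(anchors, function(an) {
        data.frame(variable = v, from = an[1], to = an[2],
                   delta = delta_metric(synced$time, synced[[v]], an[1],
                                        an[2], session$protocol),
                   stringsAsFactors = FALSE)
      }))
    }))
  })

  derived <- stage("physio", {
    end_row <- synced[which.max(synced$time), ]
    bsa <- bsa_mosteller(participant$height_cm, participant$mass_kg)
    v_end <- utils::tail(session$protocol$phases$velocity, 1)
    m_rate <- metabolic_rate(end_row$vo2, min(max(end_row$rer, 0.7), 1))
    wk <- external_work_rate(participant$mass_kg, v_end,
                             session$protocol$incline / 100)
    list(bsa_m2 = bsa,
         bmi = bmi(participant$mass_kg, participant$height_cm),
         mhp_end_w_m2 = mhp(m_rate, wk, bsa),
         core_skin_gradient_end =
           core_skin_gradient(end_row$tcore_ant, end_row$t_nv))
  })

  manifest <- list(
    stages = c("simulate", "segment", "select", "metrics", "fuse", "physio",
               "report"),
    session_id = cfg$session_id, seed = cfg$seed,
    segmentation = cfg$segmentation,
    n_frames = length(session$frames$frames),
    n_selected = length(selected),
    parameter_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]))

  run <- structure(list(session = session, masks = masks, selected = selected,
                        tsk = tsk, synced = synced, stages = stages,
                        deltas = deltas, derived = derived,
                        manifest = manifest, config = cfg),
                   class = "thermorun_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tf))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$synced, file.path(out_dir, "synchronized.csv"),
                   row.names = FALSE)
  utils::write.csv(run$stages, file.path(out_dir, "stages.csv"),
                   row.names = FALSE)
  utils::write.csv(run$deltas, file.path(out_dir, "deltas.csv"),
                   row.names = FALSE)
  utils::write.csv(run$tsk, file.path(out_dir, "tsk_samples.csv"),
                   row.names = FALSE)
  sel <- data.frame(frame_index = seq_along(run$masks) - 1L,
                    timestamp = run$session$truth_metrics$time,
                    area = vapply(run$masks, function(m) as.numeric(sum(m >= 1L)),
                                  numeric(1)),
                    selected = as.integer(seq_along(run$masks) %in%
                                            run$selected))
  utils::write.csv(sel, file.path(out_dir, "frame_selection.csv"),
                   row.names = FALSE)
  if (isTRUE(run$config$write_frames)) {
    write_sequence(run$session$frames, file.path(out_dir, "frames"))
    write_mask_stack(run$masks, file.path(out_dir, "masks"))
  }
  manifest <- run$manifest
  manifest$outputs <- as.list(tools::md5sum(list.files(out_dir,
                                                       pattern = "\\.csv$",
                                                       full.names = TRUE)))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.thermorun_run <- function(x, ...) {
  cat(sprintf("pipeline run %s (seed %d): %d frames, %d selected, %d stages\n",
              x$manifest$session_id, x$manifest$seed, x$manifest$n_frames,
              x$manifest$n_selected, nrow(x$session$protocol$phases)))
  invisible(x)
}

#' Multi-session reproducibility analysis
#'
#' Generates the three running sessions for a cohort of participants and
#' computes the reliability statistics: section-wise single-measures ICCs
#' of the non-vessel temperature (per participant and pooled, consistency
#' and agreement) over the six standard exercise sections, and
#' repeated-measures correlations of the perforator temperature against
#' heart rate and oxygen uptake over the intermittent and recovery sections.
#' By default the T_NV series come from the generator's ground truth plus
#' frame-level measurement noise (fast, cohort scale); `use_frames = TRUE`
#' runs the full frame pipeline with oracle masks per session instead.
#'
#' @param participants data frame like [participants_reference()].
#' @param sessions character vector of session ids (default all three).
#' @param params cohort [physio_params()].
#' @param scene [scene_config()] (used when `use_frames = TRUE`).
#' @param seed integer master seed.
#' @param share_physiology if TRUE (default) a participant's physiology is
#'   identical across sessions and only measurement noise differs; if FALSE
#'   each session draws fresh physiological jitter.
#' @param measurement_noise_sd frame-level T_NV measurement noise, deg C
#'   (default 0.02; ignored with `use_frames = TRUE`).
#' @param dt sampling step of the analysis series, s (default 5).
#' @param use_frames run the full frame pipeline (default FALSE).
#' @param n_boot bootstrap replicates for the rmcorr CIs (default 200).
#' @return object of class `thermorun_repro`: list with `icc` (section ICC
#'   table), `rmcorr` (panel results), `series` (long data frame).
#' @export
run_reproducibility <- function(participants = participants_reference(),
                                sessions = c("T1", "T2", "T3"),
                                params = physio_params(),
                                scene = scene_config(), seed = 1,
                                share_physiology = TRUE,
                                measurement_noise_sd = 0.02, dt = 5,
                                use_frames = FALSE, n_boot = 200) {
  if (length(sessions) < 2L) stop("need at least 2 sessions per participant")
  seed <- as.integer(seed)
  rows <- list()
  for (i in seq_len(nrow(participants))) {
    part <- as.list(participants[i, ])
    p_base <- participant_params(params, part, seed = seed + 17L * i)
    for (j in seq_along(sessions)) {
      s <- sessions[j]
      p_ij <- if (share_physiology) p_base else
        participant_params(p_base, part, seed = seed + 1000L * j + i,
                           jitter_sd = 0.1)
      sess_seed <- seed + 101L * i + 7919L * j
      if (use_frames) {
        run <- run_session_analysis(list(
          session_id = s, participant = part, seed = sess_seed,
          physio = p_ij[setdiff(names(p_ij), c("vein_offset",
                                               "perforator_offset"))],
          segmentation = "oracle"))
        sy <- run$synced
        grid <- seq(0, run$session$protocol$total_duration, by = dt)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = part$id, session = s, time = grid,
          t_nv = stats::approx(sy$time, sy$t_nv, grid, rule = 2)$y,
          t_p = stats::approx(sy$time, sy$t_p, grid, rule = 2)$y,
          hr = stats::approx(sy$time, sy$hr, grid, rule = 2)$y,
          vo2 = stats::approx(sy$time, sy$vo2, grid, rule = 2)$y,
          stringsAsFactors = FALSE)
      } else {
        prot <- build_protocol(s, part$viat_kmh)
        sim <- simulate_physiology(prot, p_ij, dt = 1, seed = sess_seed)
        grid <- seq(0, prot$total_duration, by = dt)
        tru <- sim$truth
        noise <- local_rng(sess_seed + 1L,
                           stats::rnorm(length(grid), 0, measurement_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = part$id, session = s, time = grid,
          t_nv = stats::approx(tru$time, tru$t_nv, grid, rule = 2)$y + noise,
          t_p = stats::approx(tru$time, tru$t_p, grid, rule = 2)$y + noise,
          hr = stats::approx(sim$trace$time, sim$trace$hr, grid, rule = 2)$y,
          vo2 = stats::approx(sim$trace$time, sim$trace$vo2, grid, rule = 2)$y,
          stringsAsFactors = FALSE)
      }
    }
  }
  series <- do.call(rbind, rows)
  df_tnv <- data.frame(participant = series$participant,
                       session = series$session, time = series$time,
                       value = series$t_nv, stringsAsFactors = FALSE)
  icc_table <- section_icc_report(df_tnv, standard_sections(), dt = dt)
  int_windows <- list(T2 = c(1680, 2760), T3 = c(600, 1680))
  rec_window <- c(2760, 2940)
  panels <- list()
  for (s in intersect(names(int_windows), sessions)) {
    w <- int_windows[[s]]
    d <- series[series$session == s & series$time >= w[1] &
                  series$time <= w[2], ]
    for (yv in c("hr", "vo2")) {
      fit <- rmcorr(d$participant, d[[yv]], d$t_p, n_boot = n_boot,
                    seed = seed + 31L)
      panels[[paste0("INT_", s, "_t_p_vs_", yv)]] <- fit
    }
  }
  for (s in sessions) {
    d <- series[series$session == s & series$time >= rec_window[1] &
                  series$time <= rec_window[2], ]
    fit <- rmcorr(d$participant, d$hr, d$t_p, n_boot = n_boot,
                  seed = seed + 37L)
    panels[[paste0("REC_", s, "_t_p_vs_hr")]] <- fit
  }
  structure(list(icc = icc_table, rmcorr = panels, series = series,
                 sessions = sessions, seed = seed,
                 share_physiology = share_physiology),
            class = "thermorun_repro")
}

#' @export
print.thermorun_repro <- function(x, ...) {
  pooled <- x$icc[x$icc$participant == "pooled" & x$icc$form == "consistency", ]
  cat("reproducibility analysis over", paste(x$sessions, collapse = ", "), "\n")
  cat("pooled ICC(3,1) by section:\n")
  print(pooled[, c("section", "icc", "ci_low", "ci_high", "label")],
        row.names = FALSE)
  invisible(x)
}
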