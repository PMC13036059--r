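test_that("scene and parameter constructors enforce their invariants", {
  expect_error(scene_config(vein_delta = 0.5, perforator_delta = 0.8),
               "vein_delta > perforator_delta")
  expect_error(scene_config(ambient_temp = 33), "below base_skin_temp")
  expect_error(scene_config(noise_sigma = -1), "noise_sigma")
  expect_error(scene_config(fps = 0), "fps")
  expect_error(physio_params(tau_hr = 0), "time constants")
  expect_error(physio_params(vein_offset = 0.1), "vein_offset")
})

test_that("zero-load protocol stays at baseline equilibrium", {
  prot <- constant_protocol(pct = 0, duration = 300)
  sim <- simulate_physiology(prot, noise = FALSE, lead_in = 0)
  p <- physio_params()
  expect_true(all(sim$trace$hr == p$hr_rest))
  expect_true(all(sim$trace$vo2 == p$vo2_rest))
  expect_true(all(sim$truth$t_nv == p$tnv_baseline))
  expect_true(all(sim$truth$tcore == p$tcore_baseline))
})

test_that("noise-free step responses match the analytic first-order solution", {
  p <- physio_params()
  prot <- constant_protocol(pct = 85, duration = 900)
  sim <- simulate_physiology(prot, p, noise = FALSE, lead_in = 0)
  t <- sim$trace$time
  hr_exact <- p$hr_rest + p$hr_gain * 85 * (1 - exp(-t / p$tau_hr))
  vo2_exact <- p$vo2_rest + p$vo2_gain * 85 * (1 - exp(-t / p$tau_vo2))
  expect_lt(max(abs(sim$trace$hr - hr_exact)), 1e-6)
  expect_lt(max(abs(sim$trace$vo2 - vo2_exact)), 1e-6)
})

test_that("default parameters reproduce the reported warm-up and recovery magnitudes", {
  for (s in c("T1", "T2", "T3")) {
    sim <- simulate_physiology(build_protocol(s, 12.2), noise = FALSE)
    tr <- sim$truth
    base <- tr$t_nv[tr$time == 0]
    wu_drop <- min(tr$t_nv[tr$time > 0 & tr$time <= 600]) - base
    expect_gte(wu_drop, -1.3)
    expect_lte(wu_drop, -1.1)
    # core temperature rises monotonically while running
    run_idx <- tr$time >= 0 & tr$time <= 2760
    expect_false(is.unsorted(tr$tcore[run_idx]))
  }
  # continuous session: mean post-exercise 3-min rise across the four metrics
  sim1 <- simulate_physiology(build_protocol("T1", 12.2), noise = FALSE)
  tr1 <- sim1$truth
  rises <- vapply(c("t_nv", "t_v", "t_p", "t_mean"), function(v) {
    tr1[[v]][tr1$time == 2940] - tr1[[v]][tr1$time == 2760]
  }, numeric(1))
  expect_gte(mean(rises), 1.1)
  expect_lte(mean(rises), 1.8)
})

test_that("rendered frames honour the painted construction", {
  sc <- tiny_scene(noise_sigma = 0)
  rf <- render_frame(sc, t_nv = 31.0, gait_phase = 0)
  tt <- rf$frame$temperatures
  expect_lt(abs(mean(tt[rf$mask == 2]) - (31.0 + sc$vein_delta)), 0.05)
  expect_lt(abs(mean(tt[rf$mask == 3]) - (31.0 + sc$perforator_delta)), 0.05)
  expect_equal(mean(tt[rf$mask == 1]), 31.0)
  expect_true(all(rf$mask %in% 0:3))
  comp <- EBImage::bwlabel(matrix(as.numeric(rf$mask > 0), nrow(rf$mask),
                                  ncol(rf$mask)))
  expect_equal(max(comp), 2)  # exactly two connected calves
  # vessels only inside the calves
  expect_true(all(which(rf$mask >= 2) %in% which(rf$mask >= 1)))
  # swing frames shrink the calf area
  rs <- render_frame(sc, t_nv = 31.0, gait_phase = pi)
  expect_lt(sum(rs$mask > 0), sum(rf$mask > 0))
  expect_true(rs$is_swing)
  expect_false(rf$is_swing)
})

test_that("vessel layout fails gracefully when the calf cannot hold the vessels", {
  sc <- scene_config(image_height = 24, image_width = 24,
                     perforator_count = 40)
  expect_error(render_frame(sc, 31, 0), "drawable area")
})

test_that("sessions are reproducible and share protocols across seeds", {
  part <- as.list(participants_reference()[2, ])
  sc <- tiny_scene()
  s1 <- generate_session("T2", part, scene = sc, seed = 7, frame_stride = 30)
  s2 <- generate_session("T2", part, scene = sc, seed = 7, frame_stride = 30)
  expect_identical(s1$sensors, s2$sensors)
  expect_identical(s1$truth_metrics, s2$truth_metrics)
  expect_identical(lapply(s1$frames$frames, function(f) f$temperatures),
                   lapply(s2$frames$frames, function(f) f$temperatures))
  s3 <- generate_session("T2", part, scene = sc, seed = 8, frame_stride = 30)
  expect_identical(s1$protocol, s3$protocol)  # field-by-field
  expect_false(identical(s1$frames$frames[[1]]$temperatures,
                         s3$frames$frames[[1]]$temperatures))
  # timestamps strictly increasing at the effective frame spacing
  ts <- s1$truth_metrics$time
  expect_true(all(diff(ts) > 0))
  expect_equal(max(abs(diff(ts) - 30 / sc$fps)), 0)
})

test_that("ground-truth metric ordering holds at every frame", {
  part <- as.list(participants_reference()[1, ])
  sess <- generate_session("T1", part, scene = tiny_scene(), seed = 3,
                           frame_stride = 10)
  tm <- sess$truth_metrics
  expect_true(all(tm$t_v > tm$t_p))
  expect_true(all(tm$t_p > tm$t_mean))
  expect_true(all(tm$t_mean > tm$t_nv))
  expect_error(generate_session("T9", part), "unknown session_id")
  expect_error(generate_session("T1", list(viat_kmh = -2)), "positive vIAT")
})
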