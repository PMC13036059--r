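test_that("protocols tile the session and encode the three load structures", {
  for (s in c("T1", "T2", "T3")) {
    p <- build_protocol(s, 12.2)
    ph <- p$phases
    expect_equal(ph$start[1], 0)
    expect_equal(ph$end[nrow(ph)], p$total_duration)
    expect_equal(ph$start[-1], ph$end[-nrow(ph)])  # contiguous, no overlap
    expect_equal(p$total_duration, 49 * 60)
    # equal average external load over the 36-min main block
    main <- ph[ph$start >= 600 & ph$end <= 2760, ]
    w_mean <- sum(main$pct_viat * (main$end - main$start)) /
      sum(main$end - main$start)
    expect_equal(w_mean, 85)
  }
  t1 <- build_protocol("T1", 12.2)
  expect_equal(t1$phases$velocity[t1$phases$mode == "CON"], 0.85 * 12.2)
  expect_equal(round(t1$phases$velocity[t1$phases$mode == "CON"], 2), 10.37)
  expect_equal(t1$phases$velocity[t1$phases$mode == "WALK"], 4)
  # T2 and T3 share the phase multiset with CON/INT order reversed
  t2 <- build_protocol("T2", 12.2)
  t3 <- build_protocol("T3", 12.2)
  key <- function(p) sort(paste(p$phases$mode, p$phases$pct_viat,
                                p$phases$end - p$phases$start))
  expect_equal(key(t2), key(t3))
  expect_equal(t2$phases$mode[2], "CON")
  expect_equal(t3$phases$mode[2], "INT")
  expect_error(build_protocol("T4", 12), "unknown session_id")
  expect_error(build_protocol("T1", -1), "positive")
})

test_that("Mosteller BSA and BMI reproduce the reference cohort table", {
  expect_equal(round(bsa_mosteller(178, 76.3), 2), 1.94)
  expect_equal(round(bsa_mosteller(167, 57.1), 2), 1.63)
  expect_equal(bsa_mosteller(100, 36), 1)
  expect_equal(round(bmi(76.3, 178), 1), 24.1)
  expect_equal(round(bmi(57.1, 167), 1), 20.5)
  expect_equal(bmi(25, 100), 25)
  ref <- participants_reference()
  expect_equal(round(bsa_mosteller(ref$height_cm, ref$mass_kg), 2), ref$bsa_m2)
  # the tabulated BMI column was derived from unrounded measurements, so
  # recomputation from the printed height/mass agrees only approximately
  expect_true(all(abs(bmi(ref$mass_kg, ref$height_cm) - ref$bmi) < 1.5))
  expect_lt(median(abs(bmi(ref$mass_kg, ref$height_cm) - ref$bmi)), 0.1)
  # cohort summary row
  expect_equal(round(mean(ref$mass_kg), 1), 68.4)
  expect_equal(round(mean(ref$viat_kmh), 1), 12.2)
  expect_error(bsa_mosteller(-1, 70), "positive")
})

test_that("metabolic rate uses RER-weighted energy equivalents", {
  expect_equal(metabolic_rate(1.0, 1.0), 21.13 / 60 * 1000)
  expect_equal(round(metabolic_rate(1.0, 1.0), 2), 352.17)
  expect_equal(round(metabolic_rate(1.0, 0.7), 0), 327)
  expect_equal(metabolic_rate(0, 0.85), 0)
  rers <- seq(0.7, 1.0, by = 0.01)
  expect_true(all(diff(metabolic_rate(1.2, rers)) > 0))  # monotone in RER
  expect_warning(m <- metabolic_rate(1.0, 1.2), "clamped")
  expect_equal(m, metabolic_rate(1.0, 1.0))
  expect_error(metabolic_rate(-1, 0.8), "non-negative")
})

test_that("external work, MHP, sweat loss and gradient arithmetic", {
  expect_equal(round(external_work_rate(70, 10.8, 0.015), 1), 30.9)
  expect_equal(external_work_rate(70, 10.8, 0), 0)
  expect_equal(external_work_rate(140, 10.8, 0.015),
               2 * external_work_rate(70, 10.8, 0.015))
  expect_equal(round(mhp(352.17, 30.9, 1.8), 1), 178.5)
  expect_equal(mhp(100, 100, 1.9), 0)
  expect_equal(mhp(300, 30, 2), mhp(300, 30, 1) / 2)
  expect_error(mhp(300, 30, 0), "bsa")
  expect_equal(as.numeric(sweat_loss(70.0, 69.2)), 800)
  expect_equal(as.numeric(sweat_loss(70, 70)), 0)
  expect_warning(sl <- sweat_loss(69.2, 70.0), "negative")
  expect_equal(as.numeric(sl), -800)
  expect_true(attr(sl, "flagged"))
  expect_equal(core_skin_gradient(37.5, 31.5), 6)
  expect_equal(core_skin_gradient(31, 31), 0)
  expect_equal(core_skin_gradient(37, 31), -core_skin_gradient(31, 37))
})

test_that("Dickhuth IAT recovers an analytically constructed threshold", {
  # exponential lactate curve: lactate(v) = a exp(v / 10); the lactate
  # equivalent lactate/v is minimized at v = 10, and the +1.5 mmol/L
  # crossing solves to v* = 10 * log((a e + 1.5) / a) in closed form
  a <- 2 / exp(1)
  v <- seq(6, 18, by = 2)
  lac <- a * exp(v / 10)
  closed_form <- 10 * log((a * exp(1) + 1.5) / a)
  fit <- iat_dickhuth(v, lac)
  expect_lt(abs(fit$viat - closed_form), 0.1)
  expect_lt(abs(fit$v_lt - 10), 1)
  # velocity scaling: scaling v by c with the same lactate profile scales IAT
  fit2 <- iat_dickhuth(1.3 * v, lac)
  expect_lt(abs(fit2$viat - 1.3 * fit$viat), 1e-9)
  # monotone-decreasing lactate never crosses the threshold
  expect_error(iat_dickhuth(v, rev(lac)), "beyond test range")
  expect_error(iat_dickhuth(c(8, 10, 12), c(1, 2, 3)), "4 stages")
  expect_error(iat_dickhuth(c(8, 8, 10, 12), c(1, 1, 2, 3)), "increasing")
})

test_that("delta metric anchors and window averaging", {
  tt <- seq(-10, 100, by = 1)
  step <- ifelse(tt >= 50, 3, 1)
  expect_equal(delta_metric(tt, step, 10, 90), 2)
  expect_equal(delta_metric(tt, step, 10, 40), 0)
  expect_equal(delta_metric(tt, rep(7, length(tt)), 0, 80), 0)
  prot <- build_protocol("T1", 12)
  tt2 <- seq(-10, 2940, by = 1)
  ramp <- tt2 * 0.001
  d <- delta_metric(tt2, ramp, "Pre", "WU-end", prot)
  expect_equal(d, mean(ramp[tt2 > 595 & tt2 <= 600]) -
                 mean(ramp[tt2 > -5 & tt2 <= 0]))
  expect_error(delta_metric(tt2, ramp, "Pre", "nowhere", prot), "unknown anchor")
})
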