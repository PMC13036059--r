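test_that("resampling is linear interpolation with held endpoints", {
  tt <- c(0, 1, 2, 3)
  vv <- c(0, 2, 4, 6)
  expect_equal(resample_to_timeline(tt, vv, tt), vv)
  fine <- seq(0, 3, by = 1 / 30)
  expect_equal(resample_to_timeline(tt, vv, fine), 2 * fine)
  expect_equal(resample_to_timeline(tt, vv, c(-5, 10)), c(0, 6))
  set.seed(1)
  src_t <- sort(runif(10, 0, 100))
  src_v <- rnorm(10)
  q <- runif(50, 0, 100)
  brute <- vapply(q, function(qq) {
    if (qq <= src_t[1]) return(src_v[1])
    if (qq >= src_t[10]) return(src_v[10])
    j <- max(which(src_t <= qq))
    src_v[j] + (src_v[j + 1] - src_v[j]) * (qq - src_t[j]) /
      (src_t[j + 1] - src_t[j])
  }, numeric(1))
  expect_equal(resample_to_timeline(src_t, src_v, q), brute, tolerance = 1e-12)
  expect_error(resample_to_timeline(1, 1, 1:3), "2 trace points")
})

test_that("missing-value interpolation fills interior linearly, edges nearest", {
  x <- c(1, 2, 3)
  expect_equal(interpolate_missing(x), x)
  expect_equal(interpolate_missing(c(30, NA, 32)), c(30, 31, 32))
  expect_equal(interpolate_missing(c(NA, NA, 5, NA, 7, NA)),
               c(5, 5, 5, 6, 7, 7))
  set.seed(2)
  v <- rnorm(50)
  gaps <- sample(2:49, 15)
  vg <- v; vg[gaps] <- NA
  idx <- which(!is.na(vg))
  brute <- approx(idx, vg[idx], xout = 1:50, rule = 2)$y
  expect_equal(interpolate_missing(vg), brute)
  expect_true(all(is.na(interpolate_missing(rep(NA_real_, 5)))))
})

test_that("Savitzky-Golay is exact on cubics and identity on constants", {
  t <- seq_len(400)
  p <- 1e-6 * t^3 - 4e-4 * t^2 + 0.01 * t + 2
  expect_equal(savgol_smooth(p, 151, 3), p, tolerance = 1e-8)
  expect_equal(savgol_smooth(rep(3.3, 200), 51), rep(3.3, 200))
  set.seed(3)
  noise <- rnorm(1000)
  expect_lt(var(savgol_smooth(noise, 151, 3)), var(noise))
  expect_error(savgol_smooth(1:100, 50), "odd")
  expect_error(savgol_smooth(1:100, 151), "longer than series")
  expect_error(savgol_smooth(1:100, 3, 3), "exceed polyorder")
})

test_that("zero-phase Butterworth has unit DC gain and attenuates far above cutoff", {
  expect_equal(butterworth_lowpass(rep(5, 400)), rep(5, 400), tolerance = 1e-9)
  t <- 0:999
  s <- sin(2 * pi * 0.2 * t)  # 10x the 0.02 cycles/sample cutoff
  y <- butterworth_lowpass(s)
  expect_lt(max(abs(y[200:800])), max(abs(s)) / 20)
  tr <- 0.01 * t
  yt <- butterworth_lowpass(tr)
  interior <- 300:700
  expect_lt(max(abs(yt[interior] - tr[interior]) / abs(tr[interior])), 0.01)
  expect_error(butterworth_lowpass(1:100, cutoff_normalized = 1.5), "cutoff")
  # single-pass variant also preserves DC
  y1 <- butterworth_lowpass(rep(2, 400), zero_phase = FALSE)
  expect_equal(y1, rep(2, 400), tolerance = 1e-9)
})

test_that("rolling median removes spikes and matches the naive oracle", {
  expect_equal(rolling_median(rep(4, 20), 7), rep(4, 20))
  z <- c(rep(1, 10), 100, rep(1, 10))
  expect_equal(rolling_median(z, 5), rep(1, 21))
  set.seed(4)
  x <- rnorm(200)
  for (w in c(3, 4, 35)) {
    expect_equal(rolling_median(x, w), naive_rolling_median(x, w))
  }
  xm <- sort(rnorm(100))  # monotone in, monotone out
  expect_false(is.unsorted(rolling_median(xm, 11)))
})

test_that("phase labelling splits the main block into equal halves with ramp exclusions", {
  for (s in c("T1", "T2", "T3")) {
    prot <- build_protocol(s, 12.2)
    lp <- label_phases(prot)
    ph <- lp$phases
    expect_equal(ph$phase, c("WU", "FH", "SH", "REC"))
    expect_equal(ph$end[2] - ph$start[2], 18 * 60)
    expect_equal(ph$end[3] - ph$start[3], 18 * 60)
    expect_equal(ph$start[-1], ph$end[-4])  # tiling, no overlap
    expect_equal(ph$start[1], 0)
    expect_equal(ph$end[4], prot$total_duration)
    # one exclusion interval per commanded velocity change
    v <- c(0, prot$phases$velocity)
    expect_equal(nrow(lp$exclusions), sum(abs(diff(v)) > 0))
  }
})

test_that("stage aggregation means the final window excluding ramps", {
  prot <- build_protocol("T2", 12.2)
  tt <- seq(0, prot$total_duration, by = 1)
  st <- aggregate_stage(tt, rep(7, length(tt)), prot)
  expect_true(all(st$mean == 7))
  expect_true(all(st$valid))
  expect_equal(nrow(st), nrow(prot$phases))
  # hand-computed mean of a ramp series over the final 5 s of the warm-up;
  # the sample at t = 600 sits at the commanded velocity change and is
  # excluded as part of the treadmill ramp
  v <- 0.01 * tt
  st2 <- aggregate_stage(tt, v, prot)
  expect_equal(st2$mean[st2$stage == "WU"],
               mean(v[tt > 595 & tt < 600]), tolerance = 1e-9)
  # a stage fully inside a ramp is flagged invalid
  prot_short <- constant_protocol(pct = 85, duration = 600)
  prot_short$phases <- rbind(prot_short$phases,
    data.frame(name = "BLIP", start = 600, end = 603, pct_viat = 200,
               mode = "CON", velocity = 24))
  prot_short$total_duration <- 603
  st3 <- aggregate_stage(seq(0, 603), 0.01 * seq(0, 603), prot_short)
  expect_false(st3$valid[st3$stage == "BLIP"])
})

test_that("cohort median ignores missing values elementwise", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(cohort_median_series(m), c(1, 2, 3))
  expect_equal(cohort_median_series(rbind(c(1, 2, 100))), 2)
  set.seed(5)
  mm <- matrix(rnorm(60), 20, 3)
  mm[sample(60, 10)] <- NA
  brute <- apply(mm, 1, function(r) median(r, na.rm = TRUE))
  brute[is.nan(brute)] <- NA
  expect_equal(cohort_median_series(mm), unname(brute))
  expect_true(is.na(cohort_median_series(matrix(NA_real_, 1, 3))))
})

test_that("filters preserve length and pass constants end to end", {
  set.seed(6)
  x <- rnorm(500)
  expect_length(savgol_smooth(x, 151), 500)
  expect_length(butterworth_lowpass(x), 500)
  expect_length(rolling_median(x, 350), 500)
  k <- rep(1.234, 400)
  expect_equal(rolling_median(k, 350), k)
  expect_equal(savgol_smooth(k, 151), k, tolerance = 1e-9)
  expect_equal(butterworth_lowpass(k), k, tolerance = 1e-9)
})
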