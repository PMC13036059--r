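# Independent brute-force oracles and small fixtures used across test files.

# Two-way ANOVA mean squares by explicit sum-of-squares loops.
naive_anova_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  g <- mean(mat)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(mat[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(mat[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (mat[i, j] - mean(mat[i, ]) - mean(mat[, j]) + g)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

naive_icc <- function(mat, form) {
  ms <- naive_anova_ms(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (form == "consistency") {
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  }
}

# Repeated-measures correlation via an explicit design-matrix least-squares
# fit (per-subject intercept dummies plus a common slope).
naive_rmcorr <- function(subject, x, y) {
  f <- factor(subject)
  X <- cbind(stats::model.matrix(~ f - 1), x)
  beta <- qr.solve(X, y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  X0 <- stats::model.matrix(~ f - 1)
  res0 <- y - X0 %*% qr.solve(X0, y)
  ss_x <- sum(res0^2) - sse
  unname(sign(beta[length(beta)]) * sqrt(ss_x / (ss_x + sse)))
}

# Naive per-pixel histogram entropy (bits).
naive_entropy <- function(values, bin_width, lo, hi) {
  nbins <- ceiling((hi - lo) / bin_width)
  counts <- numeric(nbins + 2)
  for (v in values) {
    i <- floor((v - lo) / bin_width + 1e-9)
    if (i < 0) i <- -1
    if (i >= nbins) i <- nbins
    counts[i + 2] <- counts[i + 2] + 1
  }
  p <- counts[counts > 0] / length(values)
  -sum(p * log2(p))
}

naive_rolling_median <- function(x, window) {
  n <- length(x)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - left):min(n, i + right)]
    w <- w[is.finite(w)]
    out[i] <- if (length(w)) median(w) else NA_real_
  }
  out
}

# A single-stage constant-load protocol (for step-response and filter tests).
constant_protocol <- function(pct = 85, duration = 600, viat = 12) {
  structure(list(session_id = "T1", viat = viat, incline = 1.5,
                 total_duration = duration,
                 phases = data.frame(name = "CON", start = 0, end = duration,
                                     pct_viat = pct, mode = "CON",
                                     velocity = pct / 100 * viat,
                                     stringsAsFactors = FALSE)),
            class = "thermorun_protocol")
}

tiny_scene <- function(...) scene_config(image_height = 48, image_width = 64,
                                         vein_count = 1, perforator_count = 2,
                                         ...)
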