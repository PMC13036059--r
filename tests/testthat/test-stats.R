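test_that("correlation matches explicit formulas and labels magnitudes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x)$r, 1)
  expect_equal(correlate(x, -x, method = "spearman")$r, -1)
  set.seed(42)
  for (i in 1:20) {
    xs <- rnorm(12); ys <- 0.4 * xs + rnorm(12)
    r_brute <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
    fit <- correlate(xs, ys)
    expect_equal(fit$r, r_brute, tolerance = 1e-12)
    ct <- cor.test(xs, ys)
    expect_equal(fit$p_value, unname(ct$p.value), tolerance = 1e-10)
    fs <- correlate(xs, ys, method = "spearman")
    expect_equal(fs$r, unname(cor(xs, ys, method = "spearman")),
                 tolerance = 1e-12)
  }
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
  expect_equal(cohen_label(c(0.05, 0.1, 0.29, 0.3, 0.49, 0.5, -0.9)),
               c("trivial", "small", "small", "moderate", "moderate",
                 "large", "large"))
})

test_that("rmcorr equals the design-matrix ANCOVA oracle", {
  # perfect within-subject linearity with subject-specific offsets
  subj <- rep(1:4, each = 5)
  x <- rep(1:5, 4)
  y <- x + rep(c(0, 10, -3, 7), each = 5)
  fit <- rmcorr(subj, x, y, n_boot = 0)
  expect_equal(fit$r_rm, 1)
  expect_equal(fit$df, length(x) - 4 - 1)
  # degenerate: no within-subject x variance
  expect_error(rmcorr(rep(1:3, each = 3), rep(1:3, each = 3), rnorm(9),
                      n_boot = 0), "within-subject")
  set.seed(7)
  for (i in 1:20) {
    ns <- sample(3:6, 1)
    subj <- rep(seq_len(ns), each = 6)
    x <- rnorm(6 * ns)
    y <- -0.5 * x + rep(rnorm(ns, sd = 3), each = 6) + rnorm(6 * ns)
    fit <- rmcorr(subj, x, y, n_boot = 0)
    expect_equal(fit$r_rm, naive_rmcorr(subj, x, y), tolerance = 1e-10)
  }
})

test_that("rmcorr reduces to Pearson when subjects share a common intercept", {
  set.seed(11)
  x1 <- rnorm(10); y1 <- 0.6 * x1 + rnorm(10, sd = 0.3)
  x1 <- x1 - mean(x1); y1 <- y1 - mean(y1)  # both subjects centered at 0
  x2 <- rnorm(10); y2 <- 0.6 * x2 + rnorm(10, sd = 0.3)
  x2 <- x2 - mean(x2); y2 <- y2 - mean(y2)
  fit <- rmcorr(rep(1:2, each = 10), c(x1, x2), c(y1, y2), n_boot = 0)
  expect_equal(fit$r_rm, unname(cor(c(x1, x2), c(y1, y2))), tolerance = 1e-12)
})

test_that("rmcorr bootstrap CI is deterministic, ordered and brackets r_rm", {
  set.seed(3)
  subj <- rep(1:6, each = 8)
  x <- rnorm(48)
  y <- -0.7 * x + rep(rnorm(6), each = 8) + rnorm(48, sd = 0.5)
  f1 <- rmcorr(subj, x, y, n_boot = 300, seed = 9)
  f2 <- rmcorr(subj, x, y, n_boot = 300, seed = 9)
  expect_identical(f1$ci_low, f2$ci_low)
  expect_lte(f1$ci_low, f1$r_rm)
  expect_gte(f1$ci_high, f1$r_rm)
  expect_lt(f1$r_rm, 0)
})

test_that("ICC matches the explicit two-way ANOVA oracle", {
  m <- matrix(rnorm(18), 6, 3)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(icc(same, "consistency")$icc, 1)
  expect_equal(icc(same, "agreement")$icc, 1)
  shifted <- cbind(m[, 1], m[, 1] + 2, m[, 1] - 1)
  expect_equal(icc(shifted, "consistency")$icc, 1)
  expect_lt(icc(shifted, "agreement")$icc, 1)
  set.seed(5)
  for (i in 1:20) {
    mm <- matrix(rnorm(6 * 3, sd = 1) + rep(rnorm(6, sd = 2), 3), 6, 3)
    expect_equal(icc(mm, "consistency")$icc, naive_icc(mm, "consistency"),
                 tolerance = 1e-10)
    expect_equal(icc(mm, "agreement")$icc, naive_icc(mm, "agreement"),
                 tolerance = 1e-10)
    # consistency is invariant to per-column constants; agreement is not
    sh <- sweep(mm, 2, c(0, 3, -2), "+")
    expect_equal(icc(sh, "consistency")$icc, icc(mm, "consistency")$icc,
                 tolerance = 1e-10)
    if (icc(mm, "consistency")$msr > icc(mm, "consistency")$mse) {
      expect_lt(icc(sh, "agreement")$icc, icc(mm, "agreement")$icc)
    }
  }
  expect_error(icc(matrix(1, 4, 3)), "zero total variance")
  expect_error(icc(matrix(rnorm(4), 4, 1)), "2 columns")
})

test_that("ICC confidence intervals bracket the estimate and rows drop listwise", {
  set.seed(6)
  m <- matrix(rnorm(30) + rep(rnorm(10, sd = 2), 3), 10, 3)
  for (form in c("consistency", "agreement")) {
    fit <- icc(m, form)
    expect_lte(fit$ci_low, fit$icc)
    expect_gte(fit$ci_high, fit$icc)
  }
  m_na <- m; m_na[3, 2] <- NA
  fit <- icc(m_na)
  expect_equal(fit$n_rows, 9)
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$icc, icc(m[-3, ])$icc)
})

test_that("reliability labels follow the conventional bands", {
  expect_equal(icc_label(c(0.49, 0.5, 0.74, 0.75, 0.9, 0.91)),
               c("poor", "moderate", "moderate", "good", "good", "excellent"))
})

test_that("median split puts the median participant in the lower group", {
  ids <- paste0("P", 1:11)
  vals <- c(16.5, 13.3, 12.2, 12.2, 12.5, 13.3, 10.7, 11.2, 9.9, 10.4, 12.5)
  sp <- median_split(ids, vals)
  expect_length(sp$low, 6)
  expect_length(sp$high, 5)
  expect_true(all(vals[match(sp$low, ids)] <= min(vals[match(sp$high, ids)])))
  # permutation invariance
  ord <- sample(11)
  sp2 <- median_split(ids[ord], vals[ord])
  expect_setequal(sp2$low, sp$low)
  # distinct sorted input splits into lower/upper halves
  sp3 <- median_split(letters[1:6], 1:6)
  expect_equal(sp3$low, c("a", "b", "c"))
  expect_equal(sp3$high, c("d", "e", "f"))
})

test_that("section ICC report matches direct icc() calls per cell", {
  set.seed(8)
  grid <- seq(0, 600, by = 5)
  base <- sin(grid / 80) * 2
  df <- do.call(rbind, lapply(c("A", "B"), function(p) {
    do.call(rbind, lapply(c("T1", "T2", "T3"), function(s) {
      data.frame(participant = p, session = s, time = grid,
                 value = base + rnorm(length(grid), sd = 0.1),
                 stringsAsFactors = FALSE)
    }))
  }))
  sections <- list(WU = list(sessions = c("T1", "T2", "T3"),
                             windows = list(T1 = c(0, 600), T2 = c(0, 600),
                                            T3 = c(0, 600))))
  rep <- section_icc_report(df, sections, dt = 5)
  dA <- df[df$participant == "A", ]
  matA <- sapply(c("T1", "T2", "T3"), function(s)
    dA$value[dA$session == s])
  direct <- icc(matA, "consistency")$icc
  got <- rep$icc[rep$participant == "A" & rep$form == "consistency"]
  expect_equal(got, direct, tolerance = 1e-12)
  # duplicated session series give ICC 1
  df_dup <- df
  df_dup$value <- rep(base, 6)
  rep_dup <- section_icc_report(df_dup, sections, dt = 5)
  expect_true(all(rep_dup$icc == 1))
})

test_that("independent noise series give near-zero ICC at large n", {
  set.seed(9)
  n <- 500
  m <- matrix(rnorm(3 * n), n, 3)
  expect_lt(abs(icc(m, "consistency")$icc), 0.2)
  expect_lt(abs(icc(m, "agreement")$icc), 0.2)
})
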