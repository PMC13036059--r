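#' Correlation with Cohen magnitude label
#'
#' Product-moment (Pearson) or rank (Spearman, average ranks for ties)
#' correlation computed from explicit sums, with a two-sided p-value from the
#' t approximation and a magnitude label following Cohen's conventions:
#' |r| < 0.1 trivial, 0.1-0.29 small, 0.3-0.49 moderate, >= 0.5 large.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @param method `"pearson"` or `"spearman"`.
#' @return object of class `thermorun_corr`: list with `r`, `n`, `p_value`,
#'   `method`, `magnitude_label`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (method == "spearman") {
    x <- rank(x)  # average ranks on ties
    y <- rank(y)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) stop("zero variance in x or y")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, n = n, p_value = p, method = method,
                 magnitude_label = cohen_label(r)),
            class = "thermorun_corr")
}

#' Cohen magnitude label for a correlation coefficient
#' @param r correlation coefficient(s).
#' @return character vector: trivial / small / moderate / large.
#' @export
cohen_label <- function(r) {
  a <- abs(r)
  ifelse(a < 0.1, "trivial",
         ifelse(a < 0.3, "small",
                ifelse(a < 0.5, "moderate", "large")))
}

#' @export
print.thermorun_corr <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (%s), n = %d, p = %.3g\n",
              x$method, x$r, x$magnitude_label, x$n, x$p_value))
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Within-subject common-slope correlation (ANCOVA with per-subject
#' intercepts), removing between-subject variability in the intercepts.
#' Computed from explicit sums on within-subject centered variables:
#' `r_rm = sum(xc*yc)/sqrt(sum(xc^2)*sum(yc^2))` with
#' `df = N - n_subjects - 1`, p from the F statistic, and a percentile
#' confidence interval from a cluster bootstrap resampling subjects with
#' replacement.
#'
#' @param subject subject identifiers (factor-like), one per observation.
#' @param x,y numeric observations.
#' @param n_boot bootstrap replicates for the CI (default 2000; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class `thermorun_rmcorr`: list with `r_rm`, `df`,
#'   `p_value`, `ci_low`, `ci_high`, `n_obs`, `n_subjects`, `slope`.
#' @export
rmcorr <- function(subject, x, y, n_boot = 2000, seed = 1, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y) & !is.na(subject)
  subject <- as.character(subject)[keep]; x <- x[keep]; y <- y[keep]
  counts <- table(subject)
  ok_subj <- names(counts)[counts >= 2L]
  if (length(ok_subj) < 2L) stop("need at least 2 subjects with >= 2 observations each")
  keep2 <- subject %in% ok_subj
  subject <- subject[keep2]; x <- x[keep2]; y <- y[keep2]
  est <- rmcorr_estimate(subject, x, y)
  if (!is.finite(est$r_rm)) stop("no within-subject variance in x or y")
  dfree <- length(x) - length(unique(subject)) - 1L
  r <- est$r_rm
  fstat <- r^2 / max(1 - r^2, .Machine$double.eps) * dfree
  p <- stats::pf(fstat, 1, dfree, lower.tail = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ids <- unique(subject)
    obs_by_subj <- split(seq_along(subject), subject)[ids]
    rs <- local_rng(seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(ids, length(ids), replace = TRUE)
        # duplicated subjects count as distinct clusters
        idx <- unlist(obs_by_subj[pick], use.names = FALSE)
        subj_b <- rep(seq_along(pick), vapply(obs_by_subj[pick], length, 1L))
        rmcorr_estimate(subj_b, x[idx], y[idx])$r_rm
      }, numeric(1))
    })
    rs <- rs[is.finite(rs)]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(rs, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(r_rm = r, df = dfree, p_value = p,
                 ci_low = ci[1], ci_high = ci[2],
                 n_obs = length(x), n_subjects = length(unique(subject)),
                 slope = est$slope),
            class = "thermorun_rmcorr")
}

rmcorr_estimate <- function(subject, x, y) {
  xs <- stats::ave(x, subject)
  ys <- stats::ave(y, subject)
  xc <- x - xs; yc <- y - ys
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx <= 0 || syy <= 0) return(list(r_rm = NA_real_, slope = NA_real_))
  sxy <- sum(xc * yc)
  list(r_rm = sxy / sqrt(sxx * syy), slope = sxy / sxx)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.thermorun_rmcorr <- function(x, ...) {
  cat(sprintf("repeated-measures correlation: r_rm = %.3f, df = %d, p = %.3g\n",
              x$r_rm, x$df, x$p_value))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (%d subjects, %d obs)\n",
                x$ci_low, x$ci_high, x$n_subjects, x$n_obs))
  }
  invisible(x)
}

#' Two-way single-measures intraclass correlation
#'
#' ICC from the two-way ANOVA decomposition of an n x k matrix (rows =
#' targets/time samples, columns = raters/sessions), single-measures forms:
#' consistency `ICC(3,1) = (MSR - MSE)/(MSR + (k-1) MSE)` and absolute
#' agreement `ICC(2,1) = (MSR - MSE)/(MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Confidence intervals follow the F-based (consistency) and
#' Shrout-Fleiss/McGraw-Wong (agreement, Satterthwaite df) constructions.
#' Reliability labels: < 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good,
#' > 0.9 excellent.
#'
#' @param mat numeric matrix, n rows x k columns; rows containing missing
#'   cells are dropped listwise (count reported).
#' @param form `"consistency"` (default) or `"agreement"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `thermorun_icc`: list with `icc`, `form`,
#'   `ci_low`, `ci_high`, `n_rows`, `k_cols`, `n_dropped`,
#'   `reliability_label`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(mat, form = c("consistency", "agreement"), conf = 0.95) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 columns")
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L) stop("need at least 2 complete rows")
  g <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sst <- sum((mat - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) stop("zero total variance")
  est <- if (form == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  alpha <- 1 - conf
  if (form == "consistency") {
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    # Satterthwaite df for the agreement interval
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  structure(list(icc = est, form = if (form == "consistency") "ICC(3,1)" else "ICC(2,1)",
                 ci_low = ci[1], ci_high = ci[2],
                 n_rows = n, k_cols = k, n_dropped = n_dropped,
                 reliability_label = icc_label(est),
                 msr = msr, msc = msc, mse = mse),
            class = "thermorun_icc")
}

#' Reliability label for ICC values
#'
#' Conventional interpretation bands: below 0.5 poor, between 0.5 and 0.75
#' moderate, between 0.75 and 0.9 good, above 0.9 excellent.
#'
#' @param icc ICC value(s).
#' @return character vector of labels.
#' @export
icc_label <- function(icc) {
  ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc <= 0.9, "good", "excellent")))
}

#' @export
print.thermorun_icc <- function(x, ...) {
  cat(sprintf("%s = %.3f (%s), 95%% CI [%.3f, %.3f], n = %d, k = %d\n",
              x$form, x$icc, x$reliability_label, x$ci_low, x$ci_high,
              x$n_rows, x$k_cols))
  if (x$n_dropped > 0) cat(sprintf("  %d incomplete rows dropped\n", x$n_dropped))
  invisible(x)
}

#' Median split of participants by an attribute
#'
#' Splits ids into a low and a high group at the median of `values`. With an
#' odd number of participants the median participant joins the lower group;
#' ties are broken by participant id.
#'
#' @param ids participant identifiers.
#' @param values numeric attribute, one per id.
#' @return list with `low` and `high` id vectors and the `median` value.
#' @export
median_split <- function(ids, values) {
  stopifnot(length(ids) == length(values))
  ord <- order(values, as.character(ids))
  n <- length(ids)
  n_low <- ceiling(n / 2)
  list(low = ids[ord[seq_len(n_low)]],
       high = ids[ord[seq.int(n_low + 1L, n)]],
       median = stats::median(values))
}

#' Section-wise ICC report for aligned temperature series
#'
#' Computes per-participant and pooled single-measures ICCs for a set of
#' exercise sections, each defined by the sessions it compares and a
#' per-session time window. Series are linearly resampled onto a common
#' relative timeline within each section (rows = time samples, columns =
#' sessions); the pooled estimate stacks the per-participant matrices.
#'
#' @param df long data frame with columns `participant`, `session`, `time`,
#'   `value`.
#' @param sections named list; each element is a list with `sessions`
#'   (character vector, length >= 2) and `windows`, a named list mapping each
#'   session to `c(start, end)` in seconds. See [standard_sections()].
#' @param dt resampling step within a section, seconds (default 5).
#' @param forms ICC forms to compute (default both).
#' @return data frame with one row per participant ("pooled" included) x
#'   section x form: `icc`, `ci_low`, `ci_high`, `label`, `n_rows`, `flagged`
#'   (TRUE when a section is missing for a participant).
#' @export
section_icc_report <- function(df, sections, dt = 5,
                               forms = c("consistency", "agreement")) {
  stopifnot(all(c("participant", "session", "time", "value") %in% names(df)))
  parts <- unique(df$participant)
  rows <- list()
  for (sec_name in names(sections)) {
    sec <- sections[[sec_name]]
    mats <- list()
    for (p in parts) {
      m <- section_matrix(df[df$participant == p, ], sec, dt)
      flagged <- is.null(m)
      if (!flagged) mats[[as.character(p)]] <- m
      for (form in forms) {
        fit <- if (flagged || nrow(m) < 2L) NULL else
          tryCatch(icc(m, form), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = as.character(p), section = sec_name, form = form,
          icc = if (is.null(fit)) NA_real_ else fit$icc,
          ci_low = if (is.null(fit)) NA_real_ else fit$ci_low,
          ci_high = if (is.null(fit)) NA_real_ else fit$ci_high,
          label = if (is.null(fit)) NA_character_ else fit$reliability_label,
          n_rows = if (is.null(fit)) 0L else fit$n_rows,
          flagged = flagged || is.null(fit), stringsAsFactors = FALSE)
      }
    }
    if (length(mats) > 0L) {
      stacked <- do.call(rbind, mats)
      for (form in forms) {
        fit <- tryCatch(icc(stacked, form), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = "pooled", section = sec_name, form = form,
          icc = if (is.null(fit)) NA_real_ else fit$icc,
          ci_low = if (is.null(fit)) NA_real_ else fit$ci_low,
          ci_high = if (is.null(fit)) NA_real_ else fit$ci_high,
          label = if (is.null(fit)) NA_character_ else fit$reliability_label,
          n_rows = if (is.null(fit)) 0L else fit$n_rows,
          flagged = is.null(fit), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

section_matrix <- function(dfp, sec, dt) {
  cols <- list()
  dur <- vapply(sec$windows, function(w) w[2] - w[1], numeric(1))
  if (length(unique(round(dur, 9))) != 1L) stop("section windows must share a duration")
  grid <- seq(0, dur[[1]], by = dt)
  for (s in sec$sessions) {
    w <- sec$windows[[s]]
    d <- dfp[dfp$session == s & dfp$time >= w[1] & dfp$time <= w[2] &
               is.finite(dfp$value), ]
    if (nrow(d) < 2L) return(NULL)
    cols[[s]] <- stats::approx(d$time - w[1], d$value, xout = grid, rule = 2)$y
  }
  do.call(cbind, cols)
}

#' Standard reproducibility sections
#'
#' The six exercise sections compared in the reliability analysis: warm-up
#' across all three sessions, the matched continuous-load pairs (T1-T2,
#' T1-T3, T2-T3), the intermittent pair (T2-T3), and recovery across all
#' three sessions. Windows are absolute session times; continuous and
#' intermittent blocks sit at different clock times in T2 and T3, so those
#' windows are aligned on relative time within the block.
#'
#' @return named list of section definitions for [section_icc_report()].
#' @export
standard_sections <- function() {
  list(
    "WU_T1T2T3" = list(sessions = c("T1", "T2", "T3"),
      windows = list(T1 = c(0, 600), T2 = c(0, 600), T3 = c(0, 600))),
    "CON_T1T2" = list(sessions = c("T1", "T2"),
      windows = list(T1 = c(600, 1680), T2 = c(600, 1680))),
    "CON_T1T3" = list(sessions = c("T1", "T3"),
      windows = list(T1 = c(1680, 2760), T3 = c(1680, 2760))),
    "CON_T2T3" = list(sessions = c("T2", "T3"),
      windows = list(T2 = c(600, 1680), T3 = c(1680, 2760))),
    "INT_T2T3" = list(sessions = c("T2", "T3"),
      windows = list(T2 = c(1680, 2760), T3 = c(600, 1680))),
    "REC_T1T2T3" = list(sessions = c("T1", "T2", "T3"),
      windows = list(T1 = c(2760, 2940), T2 = c(2760, 2940), T3 = c(2760, 2940)))
  )
}
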