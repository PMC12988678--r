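#' Mann-Whitney rank-biserial effect size
#'
#' Computes the Mann-Whitney U statistic with midranks for ties (U counts
#' pairs with `x > y`, ties contributing 1/2) and the signed rank-biserial
#' correlation `r_rb = 2U / (n1 * n2) - 1`. Positive values mean group 1
#' stochastically dominates group 2.
#'
#' @param x,y numeric samples from the two groups (non-empty).
#' @return list with `u`, `n1`, `n2`, `r_rb`, `abs_r_rb`.
#' @export
mann_whitney_rank_biserial <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  r_rb <- 2 * u / (n1 * n2) - 1
  list(u = u, n1 = n1, n2 = n2, r_rb = r_rb, abs_r_rb = abs(r_rb))
}

#' Wilcoxon signed-rank test with matched-pairs rank-biserial
#'
#' Two-sided paired Wilcoxon signed-rank test (zero differences dropped
#' before ranking; exact p-value for small tie-free samples via
#' [stats::wilcox.test()]) and the matched-pairs rank-biserial effect
#' size `(W+ - W-) / (W+ + W-)`, positive when `a` tends to exceed `b`.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `p_value`, `r_rb`, `w_pos`, `w_neg`, `n_nonzero`.
#' @export
wilcoxon_paired_rb <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(p_value = wt$p.value, r_rb = (w_pos - w_neg) / (w_pos + w_neg),
       w_pos = w_pos, w_neg = w_neg, n_nonzero = length(d))
}

#' Pooled z-scores
#'
#' Standardizes a vector to mean 0, SD 1 (n-1 denominator); used to place
#' µV amplitudes and µV² energies on a common unitless scale before
#' paired comparisons.
#'
#' @param values numeric vector, length >= 2, nonzero SD.
#' @return standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  (values - mean(values)) / s
}

#' Intraclass correlation ICC(2,1): two-way, single measure
#'
#' Absolute-agreement, single-measure intraclass correlation from the
#' two-way ANOVA mean squares of a complete subjects x visits matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param m numeric matrix, rows = subjects (n >= 2), columns = visits
#'   (k >= 2), no missing cells.
#' @return list with `icc`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC(2,1) requires a complete matrix")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 visits")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) stop("degenerate matrix: zero total variance")
  list(icc = (msr - mse) / denom, ms_rows = msr, ms_cols = msc,
       ms_error = mse, n = n, k = k)
}

#' Pearson correlation and Deming regression for method comparison
#'
#' Fits the errors-in-both-variables (Deming) line with error-variance
#' ratio `ratio` (1 = orthogonal regression) by the closed-form solution,
#' alongside the Pearson product-moment correlation.
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonzero
#'   variance).
#' @param ratio ratio of error variances (var_y_err / var_x_err),
#'   default 1.
#' @return list with `pearson_r`, `deming_slope`, `deming_intercept`,
#'   `error_variance_ratio`.
#' @export
deming_fit <- function(x, y, ratio = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) stop("zero variance in x or y")
  slope <- if (sxy == 0) {
    stop("zero covariance: Deming slope undefined up to sign")
  } else {
    (syy - ratio * sxx + sqrt((syy - ratio * sxx)^2 +
                                4 * ratio * sxy^2)) / (2 * sxy)
  }
  list(pearson_r = stats::cor(x, y), deming_slope = slope,
       deming_intercept = mean(y) - slope * mean(x),
       error_variance_ratio = ratio)
}

#' Leave-one-out SD outlier mask
#'
#' Flags values lying more than `threshold` standard deviations above the
#' mean of the remaining values (one-sided, matching an exclusion rule of
#' the form "greater than 4 SD higher than the mean of the rest"). Mean
#' and SD (n-1 denominator) are recomputed without the candidate value.
#'
#' @param values numeric vector, length >= 3.
#' @param threshold number of SDs (default 4).
#' @return logical mask, `TRUE` for flagged values.
#' @export
sd_outlier_mask <- function(values, threshold = 4) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  vapply(seq_len(n), function(i) {
    rest <- values[-i]
    values[i] > mean(rest) + threshold * stats::sd(rest)
  }, logical(1))
}

#' Stratified subject-level bootstrap benchmark of one feature against a
#' baseline
#'
#' Resamples subjects with replacement within each group (preserving
#' group sizes), recomputes the rank-biserial magnitude `|r_rb|` for the
#' candidate feature and the baseline on every resample, and summarizes
#' the improvement `delta = |r_rb|(feature) - |r_rb|(baseline)`:
#' the observed delta on the full sample, the percentile 95% CI of the
#' resampled deltas, and the one-sided bootstrap p-value
#' `p_boot = P(delta <= 0)` over resamples.
#'
#' @param subject_features data.frame with one row per subject, a `group`
#'   column (two levels) and one column per feature.
#' @param feature,baseline feature column names.
#' @param groups two group labels, effect sign = first vs second.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed; identical seeds give identical output.
#' @return object of class `perg_bootstrap`: list with `feature`,
#'   `baseline`, `observed_rrb_feature`, `observed_rrb_baseline`,
#'   `observed_delta`, `ci95`, `p_boot`, `n_iter`, `seed`, `deltas`.
#' @export
bootstrap_benchmark <- function(subject_features, feature, baseline,
                                groups = c("HV", "OND"),
                                n_iter = 1000L, seed = 1L) {
  stopifnot(all(c("group", feature, baseline) %in% names(subject_features)))
  g1 <- subject_features[subject_features$group == groups[1], ]
  g2 <- subject_features[subject_features$group == groups[2], ]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("each group needs at least 2 subjects")
  arr <- function(d1, d2, col)
    mann_whitney_rank_biserial(d1[[col]], d2[[col]])$abs_r_rb
  obs_f <- arr(g1, g2, feature)
  obs_b <- arr(g1, g2, baseline)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  deltas <- vapply(seq_len(n_iter), function(i) {
    b1 <- g1[sample.int(nrow(g1), replace = TRUE), ]
    b2 <- g2[sample.int(nrow(g2), replace = TRUE), ]
    arr(b1, b2, feature) - arr(b1, b2, baseline)
  }, numeric(1))
  structure(list(feature = feature, baseline = baseline,
                 observed_rrb_feature = obs_f,
                 observed_rrb_baseline = obs_b,
                 observed_delta = obs_f - obs_b,
                 ci95 = unname(stats::quantile(deltas, c(0.025, 0.975))),
                 p_boot = mean(deltas <= 0),
                 n_iter = n_iter, seed = seed, deltas = deltas),
            class = "perg_bootstrap")
}

#' @export
print.perg_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap benchmark: %s vs %s\n  |r_rb| = %.3f vs %.3f; delta = %.3f (95%% CI %.3f, %.3f); p_boot = %.3f [%d iterations]\n",
    x$feature, x$baseline, x$observed_rrb_feature, x$observed_rrb_baseline,
    x$observed_delta, x$ci95[1], x$ci95[2], x$p_boot, x$n_iter))
  invisible(x)
}
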