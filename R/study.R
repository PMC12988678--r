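## Feature extraction for one native-rate trace: canonical amplitudes,
## sym2 and Haar energy sets, retained-energy fraction and 7N.
.trace_features <- function(trace, fs_hz = 1700) {
  epoch <- detrend_and_pad(trace)
  mk <- find_canonical_markers(epoch, fs_hz)
  c(amp_p50_n35 = mk$amp_p50_n35, amp_n95_p50 = mk$amp_n95_p50,
    sym2_index_set(epoch), haar_index_set(epoch),
    energy_retained_pct = energy_retained_fraction(epoch),
    seven_n = seven_n(trace, fs_hz))
}

#' Feature table for a cohort
#'
#' Averages each subject's traces (across eyes within visit, then across
#' visits when `level = "subject"`) and extracts the full feature set per
#' averaged trace: canonical amplitudes |P50-N35| and |N95-P50|, the
#' seven sym2 energies, the eight Haar energies, the percent of energy
#' retained by the Haar set, and the 7N metric.
#'
#' @param cohort a curated `perg_cohort`.
#' @param level `"subject"` (one row per subject) or `"visit"` (one row
#'   per subject x visit, for reliability analyses).
#' @return data.frame with id columns plus one column per feature.
#' @export
feature_table <- function(cohort, level = c("subject", "visit")) {
  level <- match.arg(level)
  fs <- cohort$meta$fs_hz[1]
  if (level == "subject") {
    av <- subject_average(cohort)
    feats <- t(vapply(av$traces, .trace_features, numeric(19), fs_hz = fs))
    data.frame(subject_id = names(av$traces),
               group = unname(av$group[names(av$traces)]),
               feats, check.names = FALSE, row.names = NULL)
  } else {
    av <- visit_average(cohort)
    feats <- t(vapply(av$traces, .trace_features, numeric(19), fs_hz = fs))
    cbind(av$key, data.frame(feats, check.names = FALSE, row.names = NULL))
  }
}

#' Run the full PERG wavelet-biomarker study
#'
#' End-to-end orchestration: curation, subject averaging, feature
#' extraction, group summaries with rank-biserial effect sizes,
#' stratified subject-level bootstrap benchmarking of wavelet features
#' against the canonical amplitudes, test-retest ICC(2,1) when repeated
#' visits exist, method-comparison (Pearson + Deming on z-scores), and a
#' paired Wilcoxon between the top RGC wavelet feature and |N95-P50|.
#' Deterministic given the cohort and `seed`.
#'
#' @param cohort a `perg_cohort` (from [read_perg_ioba()] or
#'   [simulate_cohort()]); ignored when `sim_spec` is given.
#' @param sim_spec optional [cohort_sim_spec()]; when supplied the cohort
#'   is simulated from it.
#' @param groups the two group labels compared (first vs second).
#' @param benchmark_features features entered into the bootstrap
#'   benchmark.
#' @param baselines canonical baseline features.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param outlier_feature feature screened by the leave-one-out >4 SD
#'   rule (`NULL` disables screening).
#' @param outlier_threshold SD multiple for the screen (default 4).
#' @return object of class `perg_study` with elements `cohort_summary`,
#'   `filter_log`, `features` (subject level), `visit_features`,
#'   `summary` (group means, SDs, |r_rb| per feature), `benchmark`
#'   (one row per feature x baseline), `icc` (or `NULL`),
#'   `method_comparison`, `wilcoxon`, `excluded_subjects`, `config`.
#' @examples
#' spec <- cohort_sim_spec(n_subjects_per_group = 12, seed = 7)
#' st <- perg_study(sim_spec = spec, n_boot = 50, seed = 7)
#' print(st)
#' @export
perg_study <- function(cohort = NULL, sim_spec = NULL,
                       groups = c("HV", "OND"),
                       benchmark_features = c("sym2-D6-2", "sym2-A6-4",
                                              "sym2-mean-D63-A64",
                                              "seven_n"),
                       baselines = c("amp_p50_n35", "amp_n95_p50"),
                       n_boot = 1000L, seed = 1L,
                       outlier_feature = "sym2-D5-2",
                       outlier_threshold = 4) {
  if (!is.null(sim_spec)) cohort <- simulate_cohort(sim_spec)
  if (is.null(cohort)) stop("supply a cohort or a sim_spec")
  main <- curate(cohort, multi_visit = FALSE)
  multi <- curate(cohort, multi_visit = TRUE)
  feats <- feature_table(main, "subject")
  feats <- feats[feats$group %in% groups, , drop = FALSE]

  excluded <- character()
  if (!is.null(outlier_feature) && nrow(feats) >= 3L) {
    mask <- sd_outlier_mask(feats[[outlier_feature]], outlier_threshold)
    excluded <- feats$subject_id[mask]
    feats <- feats[!mask, , drop = FALSE]
  }

  feat_cols <- setdiff(names(feats), c("subject_id", "group"))
  g1 <- feats[feats$group == groups[1], ]
  g2 <- feats[feats$group == groups[2], ]
  summ <- do.call(rbind, lapply(feat_cols, function(f) {
    es <- mann_whitney_rank_biserial(g1[[f]], g2[[f]])
    data.frame(feature = f,
               mean_g1 = mean(g1[[f]]), sd_g1 = stats::sd(g1[[f]]),
               mean_g2 = mean(g2[[f]]), sd_g2 = stats::sd(g2[[f]]),
               abs_r_rb = es$abs_r_rb)
  }))
  names(summ)[2:5] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                        paste0("mean_", groups[2]), paste0("sd_", groups[2]))

  bench <- list(); bench_objs <- list()
  for (f in benchmark_features) for (b in baselines) {
    bb <- bootstrap_benchmark(feats, f, b, groups = groups,
                              n_iter = n_boot, seed = seed)
    bench_objs[[paste(f, b, sep = " vs ")]] <- bb
    bench[[length(bench) + 1L]] <- data.frame(
      feature = f, baseline = b, abs_r_rb = bb$observed_rrb_feature,
      delta_abs_r_rb = bb$observed_delta,
      ci_lo = bb$ci95[1], ci_hi = bb$ci95[2], p_boot = bb$p_boot)
  }
  bench <- do.call(rbind, bench)

  ## test-retest reliability on per-visit features, subjects with all
  ## visits, ICC computed on pooled z-scores as in the study design
  icc <- NULL
  visit_feats <- NULL
  kmax <- max(table(unique(multi$meta[c("subject_id", "visit")])$subject_id))
  if (kmax >= 2L) {
    visit_feats <- feature_table(multi, "visit")
    visit_feats <- visit_feats[visit_feats$group %in% groups, , drop = FALSE]
    counts <- table(visit_feats$subject_id)
    complete <- names(counts)[counts == kmax]
    vf <- visit_feats[visit_feats$subject_id %in% complete, ]
    if (length(complete) >= 2L) {
      icc <- do.call(rbind, lapply(feat_cols, function(f) {
        m <- matrix(zscore(vf[[f]])[order(vf$subject_id, vf$visit)],
                    nrow = length(complete), byrow = TRUE)
        data.frame(feature = f, icc_2_1 = icc_2_1(m)$icc,
                   n_subjects = length(complete), k_visits = kmax)
      }))
    }
  }

  ## method comparison: wavelet feature against its time-domain analog
  pairs <- list(c("sym2-D6-2", "amp_p50_n35"),
                c("sym2-A6-4", "amp_n95_p50"),
                c("sym2-mean-D63-A64", "amp_n95_p50"))
  mc <- do.call(rbind, lapply(pairs, function(p) {
    fit <- deming_fit(zscore(feats[[p[2]]]), zscore(feats[[p[1]]]))
    data.frame(feature = p[1], baseline = p[2],
               pearson_r = fit$pearson_r,
               deming_slope = fit$deming_slope,
               deming_intercept = fit$deming_intercept)
  }))

  wil <- wilcoxon_paired_rb(zscore(feats[["sym2-A6-4"]]),
                            zscore(feats[["amp_n95_p50"]]))

  structure(list(
    cohort_summary = table(feats$group),
    filter_log = main$filter_log,
    features = feats, visit_features = visit_feats,
    summary = summ, benchmark = bench, benchmark_objects = bench_objs,
    icc = icc, method_comparison = mc, wilcoxon = wil,
    excluded_subjects = excluded,
    config = list(groups = groups, baselines = baselines,
                  benchmark_features = benchmark_features,
                  n_boot = n_boot, seed = seed,
                  outlier_feature = outlier_feature,
                  outlier_threshold = outlier_threshold)),
    class = "perg_study")
}

#' @export
print.perg_study <- function(x, ...) {
  cat("PERG wavelet-biomarker study\n")
  cat("  subjects: ", paste(names(x$cohort_summary), x$cohort_summary,
                            sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$excluded_subjects))
    cat("  excluded by >", x$config$outlier_threshold, " SD rule: ",
        paste(x$excluded_subjects, collapse = ", "), "\n", sep = "")
  key <- x$summary[x$summary$feature %in%
                     c("amp_p50_n35", "amp_n95_p50", "sym2-D6-2",
                       "sym2-A6-4", "sym2-mean-D63-A64", "seven_n"), ]
  cat("  effect sizes |r_rb| (", paste(x$config$groups, collapse = " vs "),
      "):\n", sep = "")
  for (i in seq_len(nrow(key)))
    cat(sprintf("    %-18s %.3f\n", key$feature[i], key$abs_r_rb[i]))
  cat("  bootstrap benchmark (", x$config$n_boot, " iterations):\n",
      sep = "")
  for (i in seq_len(nrow(x$benchmark)))
    cat(sprintf("    %-18s vs %-12s delta=%+.3f (%.3f, %.3f) p_boot=%.3f\n",
                x$benchmark$feature[i], x$benchmark$baseline[i],
                x$benchmark$delta_abs_r_rb[i], x$benchmark$ci_lo[i],
                x$benchmark$ci_hi[i], x$benchmark$p_boot[i]))
  invisible(x)
}

#' @export
summary.perg_study <- function(object, ...) {
  print(object)
  if (!is.null(object$icc)) {
    cat("  test-retest ICC(2,1):\n")
    for (i in seq_len(nrow(object$icc)))
      cat(sprintf("    %-18s %.3f (n=%d, k=%d)\n",
                  object$icc$feature[i], object$icc$icc_2_1[i],
                  object$icc$n_subjects[i], object$icc$k_visits[i]))
  }
  cat("  method comparison (z-scored):\n")
  for (i in seq_len(nrow(object$method_comparison)))
    cat(sprintf("    %-18s vs %-12s r=%.3f slope=%.3f\n",
                object$method_comparison$feature[i],
                object$method_comparison$baseline[i],
                object$method_comparison$pearson_r[i],
                object$method_comparison$deming_slope[i]))
  cat(sprintf("  paired Wilcoxon sym2-A6-4 vs |N95-P50| (z): p=%.3f, r_rb=%.3f\n",
              object$wilcoxon$p_value, object$wilcoxon$r_rb))
  invisible(object)
}

#' Plot group-mean traces of a study
#'
#' Overlays the mean subject-averaged analysis epoch of each group, with
#' the partial reconstruction from the sym2-A6-4 cell dashed.
#'
#' @param x a `perg_study` built from a cohort whose signals are
#'   available in `x$features` subjects — the study keeps only features,
#'   so this method accepts the cohort used.
#' @param cohort the `perg_cohort` the study was run on.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.perg_study <- function(x, cohort, ...) {
  main <- curate(cohort, multi_visit = FALSE)
  av <- subject_average(main)
  t_ms <- (0:255) / main$meta$fs_hz[1] * 1000
  cols <- c(HV = "black", OND = "red")
  lines_list <- list()
  for (g in x$config$groups) {
    ids <- names(av$group)[av$group == g]
    epochs <- vapply(av$traces[ids], detrend_and_pad, numeric(256))
    m <- rowMeans(epochs)
    rec <- partial_reconstruction(
      perg_dwt(m, "sym2", 6),
      list(list(level = 6L, band = "approximation", position = 4L)))
    lines_list[[g]] <- cbind(m, rec)
  }
  y <- do.call(cbind, lines_list)
  graphics::matplot(t_ms, y, type = "l",
                    lty = rep(c(1, 2), length(lines_list)),
                    col = rep(cols[names(lines_list)], each = 2),
                    xlab = "time (ms)", ylab = "amplitude (µV)", ...)
  graphics::legend("topright", bty = "n",
                   legend = c(names(lines_list), "A6-4 reconstruction"),
                   col = c(cols[names(lines_list)], "grey40"),
                   lty = c(1, 1, 2))
  invisible(x)
}
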