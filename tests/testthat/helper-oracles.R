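# Independent brute-force oracles used across the suite.

# Dominance-count rank-biserial: (favorable - unfavorable) / (n1 n2),
# counting every (x_i, y_j) pair directly.
oracle_rank_biserial <- function(x, y) {
  fav <- sum(outer(x, y, `>`))
  unf <- sum(outer(x, y, `<`))
  (fav - unf) / (length(x) * length(y))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the nonzero differences (tie-free |d| assumed).
oracle_wilcoxon_exact_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Windowed extremum by explicit scan over every sample.
oracle_window_extremum <- function(epoch, lo_ms, hi_ms, fs_hz, what) {
  best_i <- NA
  best_v <- if (what == "min") Inf else -Inf
  for (i in seq_along(epoch)) {
    t <- (i - 1) / fs_hz * 1000
    if (t >= lo_ms && t <= hi_ms) {
      better <- if (what == "min") epoch[i] < best_v else epoch[i] > best_v
      if (better) { best_v <- epoch[i]; best_i <- i }
    }
  }
  c(i = best_i, v = best_v)
}

# Tiny deterministic archive-shaped cohort for curation tests.
toy_cohort <- function() {
  mk <- function(trace_id, record_id, sid, eye, visit, date, diag,
                 sec = "", comments = "", va = 0.1) {
    data.frame(trace_id = trace_id, record_id = record_id,
               subject_id = sid, eye = eye, visit = visit,
               visit_date = date, diagnosis = diag,
               diagnosis_secondary = sec, comments = comments,
               va_logmar = va, group = NA_character_, fs_hz = 1700)
  }
  meta <- rbind(
    mk("r1_LE", "r1", "s1", "LE", 1, "2020-01-01", "Normal"),
    mk("r2_LE", "r2", "s2", "LE", 1, "2020-01-01", "Normal",
       comments = "Mercury Poisoning suspected"),
    mk("r3_LE", "r3", "s3", "LE", 1, "2020-01-01", "Optic neuropathy",
       va = NA_real_),
    mk("r4_LE", "r4", "s4", "LE", 1, "2020-01-01", "Inherited optic atrophy"),
    mk("r5_LE", "r5", "s4", "LE", 2, "2020-06-01", "Inherited optic atrophy"),
    mk("r6_LE", "r6", "s5", "LE", 1, "2020-01-01", "Normal"))
  signals <- setNames(lapply(1:6, function(i) rep(i, 255)), meta$trace_id)
  pergwave:::new_perg_cohort(meta, signals)
}
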