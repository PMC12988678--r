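#' Specification of a synthetic PERG cohort
#'
#' Builds the generative model used to emulate PERG-archive data with
#' known ground truth: each trace is a sum of Gaussian-bump components
#' (the canonical N35 trough, P50 peak, N95 trough and a late
#' low-frequency retinal-ganglion-cell component near 120 ms), scaled by
#' multiplicative log-normal subject- and visit-level random effects and a
#' per-group attenuation profile, plus zero-mean Gaussian noise band-
#' limited to the 1-100 Hz hardware band.
#'
#' The default OND (optic nerve disease) profile attenuates the N95 and
#' LATE components to 0.35 of their healthy-volunteer amplitude, leaving
#' the cone-driven N35/P50 complex untouched; this makes the late
#' 112-150 ms / 0-13 Hz energy cell the sensitive feature by construction.
#'
#' @param n_subjects_per_group subjects per group (default 50).
#' @param visits_per_subject visits per subject (default 1).
#' @param eyes eyes recorded per visit (default both, `c("LE", "RE")`).
#' @param components data.frame with columns `label`, `center_ms`,
#'   `width_ms` (Gaussian SD, ms), `amplitude_uv` (signed µV; negative
#'   for troughs).
#' @param group_attenuation named list: group -> named numeric vector of
#'   per-component scale factors in `[0, 1]` (components absent from the
#'   vector keep factor 1).
#' @param subject_sd,visit_sd SDs of the log-normal subject- and
#'   visit-level multiplicative effects (log scale).
#' @param noise_sd_uv RMS of the band-limited noise in µV.
#' @param noise_band_hz two-element pass band (Hz).
#' @param fs_hz sampling rate (default 1700).
#' @param epoch_ms epoch duration (default 150; 255 samples at 1700 Hz).
#' @param seed integer seed governing the whole cohort.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects_per_group = 50L,
                            visits_per_subject = 1L,
                            eyes = c("LE", "RE"),
                            components = default_perg_components(),
                            group_attenuation = list(
                              HV = c(),
                              OND = c(N95 = 0.35, LATE = 0.35)),
                            subject_sd = 0.3,
                            visit_sd = 0.1,
                            noise_sd_uv = 0.25,
                            noise_band_hz = c(1, 100),
                            fs_hz = 1700,
                            epoch_ms = 150,
                            seed = 20260101L) {
  stopifnot(n_subjects_per_group >= 1L, visits_per_subject >= 1L,
            length(eyes) >= 1L, nrow(components) >= 1L,
            subject_sd >= 0, visit_sd >= 0, noise_sd_uv >= 0,
            all(components$width_ms > 0),
            all(components$center_ms >= 0 & components$center_ms <= epoch_ms),
            fs_hz > 2 * noise_band_hz[2])
  for (g in names(group_attenuation)) {
    att <- group_attenuation[[g]]
    if (length(att) && (any(att < 0) || any(att > 1)))
      stop("attenuation factors must lie in [0, 1]")
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 visits_per_subject = as.integer(visits_per_subject),
                 eyes = eyes, components = components,
                 group_attenuation = group_attenuation,
                 subject_sd = subject_sd, visit_sd = visit_sd,
                 noise_sd_uv = noise_sd_uv, noise_band_hz = noise_band_hz,
                 fs_hz = fs_hz, epoch_ms = epoch_ms,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Default canonical PERG component template
#'
#' Troughs at 35 and 95 ms, a peak at 50 ms, and a late low-frequency
#' component centred at 120 ms with a 15-ms SD so that its energy
#' concentrates in the 112-150 ms / 0-13 Hz dyadic cell.
#'
#' @return data.frame of component parameters.
#' @export
default_perg_components <- function() {
  data.frame(label = c("N35", "P50", "N95", "LATE"),
             center_ms = c(35, 50, 95, 120),
             width_ms = c(5, 8, 12, 15),
             amplitude_uv = c(-2, 3, -3, -2))
}

## Band-limited Gaussian noise via an FFT brick-wall mask. The white-noise
## draw is scaled by sqrt(n / kept bins) so the band-limited RMS equals sd.
.bandlimited_noise <- function(n, sd, band_hz, fs_hz) {
  if (sd == 0) return(numeric(n))
  freqs <- (seq_len(n) - 1L) * fs_hz / n
  freqs <- pmin(freqs, fs_hz - freqs)           # two-sided spectrum
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep)) return(numeric(n))
  w <- stats::fft(stats::rnorm(n))
  w[!keep] <- 0
  Re(stats::fft(w, inverse = TRUE)) / n * sd * sqrt(n / sum(keep))
}

#' Simulate a single PERG trace
#'
#' Evaluates the group-attenuated, scale-multiplied Gaussian components on
#' the sample grid and adds band-limited noise drawn from the current RNG
#' state (so a prior `set.seed()` makes the trace reproducible).
#'
#' @param spec a [cohort_sim_spec()].
#' @param group group label; must appear in `spec$group_attenuation`.
#' @param subject_scale,visit_scale positive multiplicative effects.
#' @return numeric vector of `floor(fs_hz * epoch_ms / 1000)` µV samples
#'   (255 at the defaults).
#' @export
simulate_trace <- function(spec, group, subject_scale = 1, visit_scale = 1) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (subject_scale <= 0 || visit_scale <= 0)
    stop("scales must be positive")
  if (!group %in% names(spec$group_attenuation))
    stop("unknown group ", group)
  n <- floor(spec$fs_hz * spec$epoch_ms / 1000)
  t_ms <- (seq_len(n) - 1L) / spec$fs_hz * 1000
  att <- spec$group_attenuation[[group]]
  x <- numeric(n)
  for (i in seq_len(nrow(spec$components))) {
    cmp <- spec$components[i, ]
    a <- cmp$amplitude_uv * subject_scale * visit_scale
    if (cmp$label %in% names(att)) a <- a * att[[cmp$label]]
    x <- x + a * exp(-(t_ms - cmp$center_ms)^2 / (2 * cmp$width_ms^2))
  }
  x + .bandlimited_noise(n, spec$noise_sd_uv, spec$noise_band_hz, spec$fs_hz)
}

#' Simulate a full PERG cohort
#'
#' Generates one recording per subject x visit x eye for each group in
#' `spec$group_attenuation`, with subject effects shared across all of a
#' subject's recordings (inducing nonzero test-retest ICC) and visit
#' effects shared across eyes within a visit. Synthetic visual acuities
#' and visit dates are attached so the result mirrors an archive read.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return a `perg_cohort` object (see [read_perg_ioba()]): `meta`
#'   data.frame, named `signals` list and an empty `filter_log`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  groups <- names(spec$group_attenuation)
  meta <- list(); signals <- list()
  rec <- 0L
  for (g in groups) {
    diag_label <- if (g == "HV") "Normal" else "Optic neuropathy"
    for (s in seq_len(spec$n_subjects_per_group)) {
      sid <- sprintf("%s%03d", g, s)
      s_scale <- exp(stats::rnorm(1, 0, spec$subject_sd))
      va_base <- if (g == "HV") 0.1 else 0.6
      for (v in seq_len(spec$visits_per_subject)) {
        v_scale <- exp(stats::rnorm(1, 0, spec$visit_sd))
        date <- sprintf("2020-%02d-%02d", (v - 1L) %% 12L + 1L,
                        (s - 1L) %% 28L + 1L)
        rec <- rec + 1L
        for (eye in spec$eyes) {
          trace_id <- sprintf("rec%04d_%s", rec, eye)
          meta[[trace_id]] <- data.frame(
            trace_id = trace_id,
            record_id = sprintf("rec%04d", rec),
            subject_id = sid, eye = eye, visit = v, visit_date = date,
            diagnosis = diag_label, diagnosis_secondary = "",
            comments = "",
            va_logmar = round(max(0, va_base +
                                    stats::rnorm(1, 0, 0.1)), 2),
            group = g, fs_hz = spec$fs_hz)
          signals[[trace_id]] <-
            simulate_trace(spec, g, s_scale, v_scale)
        }
      }
    }
  }
  new_perg_cohort(do.call(rbind, c(meta, make.row.names = FALSE)), signals)
}
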