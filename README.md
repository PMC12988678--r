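# pergwave

Wavelet energy biomarkers for the pattern electroretinogram (PERG).

The PERG — the retinal response to a contrast-reversing checkerboard —
is conventionally summarised by two peak-to-trough amplitudes,
|P50–N35| (macular cone function) and |N95–P50| (retinal ganglion cell,
RGC, function). These scalar measures discard the waveform's joint
time–frequency structure. `pergwave` implements the wavelet
alternative for researchers in visual electrophysiology: an orthonormal
dyadic discrete wavelet transform (DWT, periodic extension) of the
150-ms / 256-sample epoch whose squared coefficients ("energy indices",
µV²) localise physiological generators in dyadic time–frequency cells,
together with the statistical machinery needed to ask whether a given
cell beats the canonical amplitudes at separating patient groups.

For a trace $x$ and orthonormal filter pair $(h, g)$, the analysis step
with periodic extension is

$$a_k = \sum_m h_m\,x_{(2k+L/2-m) \bmod n},\qquad
  d_k = \sum_m g_m\,x_{(2k+L/2-m) \bmod n},$$

iterated on $a$ to the desired depth. An energy index such as
sym2–A6-4 is the square of the fourth level-6 approximation
coefficient of the Symlet-2 decomposition, nominally covering
112–150 ms and 0–13 Hz — the late, low-frequency window where RGC
activity concentrates. The package provides:

* the DWT engine for sym2, Haar and db8 with exact Parseval
  conservation, perfect reconstruction, partial reconstruction and
  percent-energy scalograms (`perg_dwt`, `perg_idwt`,
  `partial_reconstruction`, `scalogram`, `nominal_window`);
* the retained feature sets: five sym2 energies plus two combined
  means, eight Haar cells with the top-ten selection procedure and the
  retained-energy fraction, and the db8-derived 7N metric on its own
  2839-Hz / 512-sample grid (`sym2_index_set`, `haar_index_set`,
  `rank_indices_by_mean_energy`, `energy_retained_fraction`,
  `seven_n`);
* preprocessing and canonical markers: 0th-order detrend, duplication
  padding to 256 samples, windowed N35/P50/N95 extraction and the two
  canonical amplitudes (`detrend_and_pad`, `find_canonical_markers`);
* archive ingestion and curation with a per-rule filter log, plus
  subject averaging across eyes and visits (`read_perg_ioba`,
  `curate`, `subject_average`);
* a synthetic PERG cohort generator with known ground truth —
  Gaussian-bump morphology, log-normal subject/visit effects,
  band-limited noise, group-specific attenuation
  (`cohort_sim_spec`, `simulate_cohort`, `write_cohort_csv`);
* statistics: Mann–Whitney rank-biserial effect sizes, exact paired
  Wilcoxon, ICC(2,1) reliability, Deming regression, a leave-one-out
  >4 SD outlier screen, and a stratified subject-level bootstrap that
  benchmarks any feature against a canonical baseline
  (`mann_whitney_rank_biserial`, `wilcoxon_paired_rb`, `icc_2_1`,
  `deming_fit`, `sd_outlier_mask`, `bootstrap_benchmark`);
* `perg_study()`, a one-call orchestrator returning a classed object
  with `print`, `summary` and `plot` methods.

See `vignettes/perg-wavelet-methods.Rmd` for the full methods account.

## Worked example

Simulate a two-group cohort (healthy volunteers vs an optic-nerve-
disease profile that attenuates the N95 and late RGC components to
0.35), run the whole study, and benchmark the late low-frequency cell
against the canonical amplitudes:

```r
library(pergwave)
spec <- cohort_sim_spec(n_subjects_per_group = 20,
                        visits_per_subject = 2, seed = 42)
st <- perg_study(sim_spec = spec, n_boot = 500, seed = 42)
summary(st)
```

```
PERG wavelet-biomarker study
  subjects: HV=19, OND=19
  excluded by >4 SD rule: HV020, OND015
  effect sizes |r_rb| (HV vs OND):
    amp_p50_n35        0.091
    amp_n95_p50        0.717
    sym2-D6-2          0.025
    sym2-A6-4          0.972
    sym2-mean-D63-A64  0.961
    seven_n            0.402
  bootstrap benchmark (500 iterations):
    sym2-D6-2          vs amp_p50_n35  delta=-0.066 (-0.227, 0.191) p_boot=0.598
    ...
    sym2-A6-4          vs amp_n95_p50  delta=+0.255 (0.075, 0.482) p_boot=0.002
  test-retest ICC(2,1):
    amp_n95_p50        0.893 (n=40, k=2)
    sym2-A6-4          0.915 (n=40, k=2)
    ...
  method comparison (z-scored):
    sym2-D6-2          vs amp_p50_n35  r=0.957 slope=1.000
    sym2-A6-4          vs amp_n95_p50  r=0.953 slope=1.000
    ...
  paired Wilcoxon sym2-A6-4 vs |N95-P50| (z): p=0.943, r_rb=0.015
```

Reading the output: the cone-driven features (|P50–N35|, sym2–D6-2)
barely separate the groups — by construction the OND profile spares the
cone complex — while the late cell sym2–A6-4 separates them almost
completely (|r_rb| = 0.97) and significantly out-benchmarks both
canonical amplitudes (positive Δ|r_rb| with one-sided bootstrap
p = 0.002 against |N95–P50|). Wavelet features track their time-domain
analogues tightly (Pearson r ≈ 0.95 on z-scores) and show good-to-
excellent test–retest reliability (ICC(2,1) ≥ 0.9 for the late cells).
Two subjects were excluded by the leave-one-out >4 SD screen on
sym2–D5-2.

Ingesting an archive instead of simulating works through the same
object:

```r
paths <- list.files("archive/", pattern = "\\.csv$", full.names = TRUE)
co <- read_perg_ioba(setdiff(paths, "archive/metadata.csv"),
                     "archive/metadata.csv")
st <- perg_study(cohort = co, n_boot = 1000, seed = 1)
```

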