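---
title: "Wavelet energy biomarkers for the pattern electroretinogram: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet energy biomarkers for the pattern electroretinogram: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pergwave)
```

## The problem

The pattern electroretinogram (PERG) is the retinal response to a
contrast-reversing checkerboard. Its canonical waveform holds a trough
near 35 ms (N35), a peak near 50 ms (P50, dominated by macular cones)
and a trough near 95 ms (N95, dominated by retinal ganglion cells,
RGCs). Clinical practice summarises the waveform with two peak-to-trough
amplitudes, |P50–N35| and |N95–P50|, which discard most of the signal's
time–frequency structure. `pergwave` implements an alternative: an
orthogonal dyadic discrete wavelet transform (DWT) of the 150-ms epoch,
whose squared coefficients ("energy indices") localise physiological
generators in joint time–frequency cells, and a statistical layer that
benchmarks those indices against the canonical amplitudes. Optic nerve
disease (OND), which preferentially degrades RGC output, is the working
contrast: a late, low-frequency energy cell should lose energy in OND
while the cone-driven P50 region is relatively spared.

## Pipeline

1. **Curation** (`curate()`): traces are grouped into OND (diagnoses
   "Inherited optic atrophy", "Bilateral optic atrophy", "Optic
   neuropathy") and healthy volunteers (diagnosis exactly "Normal" with
   an empty secondary-diagnosis field — a deliberately conservative,
   auditable rule); traces whose comments mention mercury poisoning
   (case-insensitive substring, since the field is free text) and traces
   without a visual acuity are removed; by default only each subject's
   first visit is kept, with a `multi_visit` mode for reliability
   analyses. Every rule logs its removal count, and because the rules
   are conjunctive predicates the retained set is order-independent.
2. **Averaging** (`subject_average()`): pointwise mean across eyes and
   repeats within a visit, then across visits — one trace per subject,
   appropriate for bilateral conditions and avoiding pseudoreplication.
3. **Preprocessing** (`detrend_and_pad()`): the 255-sample epoch (150 ms
   at 1700 Hz) is de-meaned (0th-order polynomial detrend) and its last
   sample duplicated once to reach 256 = 2^8 points. The epoch is read
   as starting at stimulus onset: the marker windows (25–115 ms) only
   exist post-onset, so an onset-centred reading would be inconsistent
   with them.
4. **Markers** (`find_canonical_markers()`): windowed extrema with
   inclusive endpoints and earliest-sample tie-breaks — deterministic
   and reproducible where a manual-verification step cannot be.
5. **Wavelet features** (`perg_dwt()`, `sym2_index_set()`,
   `haar_index_set()`, `seven_n()`): described below.
6. **Statistics** (`mann_whitney_rank_biserial()`, `icc_2_1()`,
   `bootstrap_benchmark()`, `deming_fit()`, …): described below.
7. **Orchestration** (`perg_study()`): runs 1–6 and returns a classed
   object with `print`, `summary` and `plot` methods.

## The wavelet engine

`perg_dwt()` implements the orthonormal dyadic DWT with *periodic*
("per") extension for three mother wavelets: Symlet-2 (two vanishing
moments; identical to Daubechies-2), Haar (shortest filter, linear
phase) and Daubechies-8. The analysis step is

$$a_k = \sum_m h_m\, x_{(2k + L/2 - m) \bmod n}, \qquad
  d_k = \sum_m g_m\, x_{(2k + L/2 - m) \bmod n},$$

with $g_m = (-1)^{m+1} h_{L-1-m}$. The $L/2$ phase keeps coefficient
$k$ time-aligned with samples $\approx [2k, 2k+1]$, so that the
$k$-th coefficient of level $j$ nominally covers the interval
$[(k-1)\,2^j,\ k\,2^j)$ samples — the alignment that underpins the
printed window labels. For even $n$ the transform matrix is orthogonal,
so the inverse is its adjoint, energy is conserved exactly (Parseval)
and reconstruction is exact to floating-point rounding; both properties
are asserted at `1e-9` relative tolerance in the tests, and the
coefficients are cross-checked against an independent wavelet library.

Filter taps are embedded as published double-precision constants and
verified in the tests by their defining properties (sum $\sqrt2$, unit
norm, orthogonality under even shifts, vanishing moments).

**Window labels.** `nominal_window()` labels level-$j$ position-$k$
cells on a *nominal* grid of 150 ms / 256 samples / 1700 Hz, although
256 samples at 1700 Hz strictly span 150.6 ms: the nominal grid is what
reproduces the conventional band edges (27/53, 13/27, 7/13 Hz). Edges
are rounded half-to-even, which uniquely maps 37.5 → 38 and
112.5 → 112. Under this rule the level-5 position-2 detail cell spans
19–38 ms; a 17–38 ms label sometimes quoted for that cell does not
follow from the dyadic rule and is not produced here.

**Feature sets.** The sym2 set keeps five energies — D5-2, D6-2, D6-3,
A6-3, A6-4 of a six-level decomposition — plus the combined features
mean(D6-2, A6-3) and mean(D6-3, A6-4) (arithmetic means of the two
energies). The Haar set keeps eight cells of a seven-level
decomposition: A7-1/2, D7-1/2, D6-2, D5-2/3/4.
`rank_indices_by_mean_energy()` reproduces the selection procedure
behind the Haar set: rank all retained cells (details D4 and deeper
plus the final approximation; D1–D3 lie at 106–850 Hz, above the
1–100 Hz analog band, and non-final approximations duplicate retained
details) by mean energy over healthy traces and keep the top ten.
`energy_retained_fraction()` reports the percent of total energy the
selected cells capture. Scalograms (`scalogram()`) are emitted as raw
per-cell percent-of-total-energy grids, with no interpolation or
smoothing.

## The 7N metric

`seven_n()` reproduces a glaucoma-derived RGC index defined on a
different grid: the native trace is resampled to 2839 Hz, zero-padded
to 512 samples, min-max normalised onto $[-2, +2]$, decomposed to seven
levels with db8, and summarised as
$7N = 100\, e_3 / (e_1+e_2+e_3+e_4)$ where $e_i$ is the squared $i$-th
level-7 detail coefficient. Three choices the original definition
leaves open are fixed here and exposed where reasonable:

* **Resampling** is Fourier-domain rate conversion at the exact ratio
  2839/1700 (`fourier_resample()`), i.e. band-limited sinc
  interpolation of the periodically extended signal; a polyphase
  alternative would introduce filter-dependent phase shifts.
* **Normalisation order**: the listed order (pad, then normalise) is
  the default; `normalize_before_pad = TRUE` gives the alternative,
  which differs whenever the trace does not cross zero.
* **Extension mode** is periodic, consistent with the rest of the
  package.

Because min-max normalisation removes scale, 7N is invariant to global
amplitude scaling of the raw trace. The dyadic window of the D7-3 cell
at 2839 Hz does not coincide exactly with the 90–135 ms / 11–22 Hz
label sometimes attached to 7N; window labels here always come from the
dyadic rule.

## Statistics

* **Effect size**: Mann–Whitney U with midranks; signed rank-biserial
  $r_{rb} = 2U/(n_1 n_2) - 1$, positive when the healthy group
  stochastically dominates. Group tables report $|r_{rb}|$.
* **Paired comparison**: Wilcoxon signed-rank on pooled z-scores
  (z-scoring removes the µV vs µV² unit difference); matched-pairs
  rank-biserial $(W^+ - W^-)/(W^+ + W^-)$. The p-value is exact for
  small tie-free samples.
* **Reliability**: ICC(2,1), the two-way absolute-agreement
  single-measure intraclass correlation
  $\mathrm{ICC} = (MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$,
  computed from a complete subjects × visits matrix of z-scored
  features.
* **Method comparison**: Pearson correlation plus closed-form Deming
  regression with error-variance ratio 1 (orthogonal fit) — both
  variables are measured with error, so ordinary least squares would
  bias the slope.
* **Outlier screen**: a leave-one-out rule flags values more than 4 SD
  above the mean of the *remaining* values (one-sided by design:
  energy outliers of interest are large); applied to sym2–D5-2 by
  default and configurable off.
* **Benchmark**: a stratified subject-level bootstrap (default 1000
  iterations, fixed seed) resamples subjects with replacement within
  each group, recomputes $|r_{rb}|$ for a candidate feature and a
  canonical baseline on every resample, and reports the observed
  $\Delta|r_{rb}|$, the percentile 95% CI of the resampled deltas, and
  the one-sided $P_{boot} = \Pr(\Delta \le 0)$ with the weak
  inequality. Percentile rather than BCa intervals are used: the
  benchmarked statistic is a bounded difference of bounded effect
  sizes, where the plain percentile interval is adequate and simpler
  to reason about. Resampling operates on precomputed subject-level
  features (the subject is the exchangeable unit); SDs use the $n-1$
  denominator throughout.

## The synthetic cohort generator

No public generative model exists for PERG cohorts, so
`cohort_sim_spec()` defines one *as a fixture with known ground truth*,
not as a claim about real retinas. Each trace is

$$x(t) = s_i\, v_{ij} \sum_c \alpha_{g,c}\, A_c\,
  e^{-(t-\mu_c)^2/2\sigma_c^2} + \varepsilon(t),$$

with Gaussian bumps for N35 (−2 µV, 35 ms, SD 5 ms), P50 (+3 µV,
50 ms, SD 8 ms), N95 (−3 µV, 95 ms, SD 12 ms) and a late RGC component
LATE (−2 µV, 120 ms, SD 15 ms) whose energy concentrates in the
112–150 ms / 0–13 Hz cell by construction; log-normal multiplicative
subject ($s_i$, log-SD 0.3) and visit ($v_{ij}$, log-SD 0.1) effects —
amplitudes are positive-scaled physiological quantities, so
multiplicative effects keep them positive and induce a nonzero ICC;
and noise $\varepsilon$ synthesised as white Gaussian, band-limited to
the 1–100 Hz hardware band by an FFT brick-wall mask and scaled by the
theoretical $\sqrt{n/\text{kept bins}}$ factor so `noise_sd_uv`
(default 0.25 µV, a plausible residual after ~100-sweep averaging) is
the band-limited RMS. The brick-wall edge is deliberate: it is exactly
reproducible and leaves no filter-order choice. The OND profile scales
N95 and LATE by 0.35 and leaves the cone complex untouched; amplitudes
and widths were fixed once when the generator was designed.

What the generator does *not* emulate: sharp non-Gaussian transients
(so the 27–53 Hz band is weakly excited and the highest-frequency
retained Haar cell, D5-2, can rank just below the top ten where real
N35 transients would push it higher), artifacts, drift, eye asymmetries
beyond independent noise, and any disease physiology beyond the
attenuation profile. Passing tests on this fixture therefore
demonstrate correctness of the machinery and the *direction* of the
group contrasts, not clinical performance on archive data.

## Numerical and design choices

* Marker windows are endpoint-inclusive with earliest-sample
  tie-breaks; a flat trace yields markers at the window starts and zero
  amplitudes.
* Inputs already 256 samples long skip duplication; shorter inputs are
  padded by repeated duplication with a warning.
* `detrend_and_pad()` refuses inputs over 256 samples rather than
  truncating silently.
* Degenerate cases raise errors instead of returning sentinel values:
  constant traces in 7N normalisation, zero-energy traces in
  scalograms, zero-SD vectors in z-scoring, incomplete matrices in
  ICC.
* Determinism: `simulate_cohort()` and `bootstrap_benchmark()` seed a
  local RNG stream and restore the caller's RNG state; identical seeds
  give bit-identical cohorts and resample paths.
* Problem sizes in the tests and the acceptance script — 50 subjects
  per group, two visits, 1000 bootstrap iterations, 100-trace Parseval
  sweeps, 500-subject ICC recovery — were chosen as the smallest sizes
  at which the checked properties are stable, keeping the whole suite
  fast enough to run routinely.

## Known limitations

* Dyadic localisation is fixed: latency shifts spread energy across
  neighbouring cells. Adaptive (e.g. local-maximum) methods address
  this at the cost of orthogonality and are out of scope.
* The curation rules are exact-match/substring heuristics on free-text
  metadata; the reader's column mapping is configurable, but archive
  dialects beyond the CSV layout written by `write_cohort_csv()` are
  untested.
* Whether reliability analyses should use first-visit-only or
  multi-visit record sets is genuinely ambiguous in practice; both
  modes are exposed (`curate(..., multi_visit = TRUE)`) and the study
  object computes its ICC from the multi-visit set while the main
  group comparison uses first visits only.
* The multiplicative-effects generator cannot separate amplitude
  reliability from energy reliability; ICC values on the fixture are
  typically higher than archive values.
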