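Package: pergwave
Title: Wavelet Energy Biomarkers for the Pattern Electroretinogram
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting time-frequency biomarkers from pattern
    electroretinogram (PERG) recordings. Implements the dyadic discrete
    wavelet transform with periodic extension for the Symlet-2, Haar and
    Daubechies-8 mother wavelets; coefficient energy indices with nominal
    time-frequency window labels; partial reconstruction and percent-energy
    scalograms; the db8-derived 7N metric; canonical N35/P50/N95 marker and
    amplitude extraction; cohort curation for PERG archives; a synthetic
    PERG cohort generator with known ground truth; and the statistical
    layer used to benchmark wavelet features against canonical amplitudes
    (Mann-Whitney rank-biserial effect sizes, Wilcoxon signed-rank tests,
    ICC(2,1) test-retest reliability, Deming regression, leave-one-out
    outlier screening, and a stratified subject-level bootstrap).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
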