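#' Detrend a PERG epoch and pad it to 256 samples
#'
#' Removes the DC offset by fitting a 0th-order polynomial (the sample
#' mean) and subtracting it, then duplicates the final sample until the
#' trace holds exactly 256 points, the power-of-two length required for
#' dyadic decomposition. A native 150-ms epoch at 1700 Hz has 255 samples
#' and is duplicated once; shorter traces are padded repeatedly with a
#' warning.
#'
#' @param samples numeric vector of raw µV samples, 2 to 256 long.
#' @return numeric vector of exactly 256 samples, zero-mean before the
#'   padding samples were appended.
#' @export
detrend_and_pad <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (n > 256L) stop("epoch has ", n, " samples; at most 256 supported")
  x <- as.numeric(samples) - mean(samples)
  if (n < 255L)
    warning("epoch shorter than 255 samples; padding ", 256L - n,
            " duplicates")
  c(x, rep(x[n], 256L - n))
}

## 0-based sample index -> milliseconds on the native grid.
.sample_time_ms <- function(i, fs_hz = 1700) i / fs_hz * 1000

#' Locate the canonical N35, P50 and N95 markers
#'
#' Finds the canonical deflections on fixed latency windows relative to
#' stimulus onset (sample 0): N35 is the most negative sample within
#' 25-40 ms, P50 the most positive within 40-60 ms, and N95 the most
#' negative within 85-115 ms. Window endpoints are inclusive; ties are
#' broken by the earliest sample. Amplitudes are the absolute differences
#' |P50-N35| and |N95-P50|.
#'
#' @param epoch a 256-sample analysis trace from [detrend_and_pad()].
#' @param fs_hz native sampling rate in Hz (default 1700).
#' @return a one-row data.frame with marker times (ms), marker voltages
#'   (µV) and the two canonical amplitudes `amp_p50_n35`, `amp_n95_p50`.
#' @export
find_canonical_markers <- function(epoch, fs_hz = 1700) {
  stopifnot(length(epoch) == 256L)
  t_ms <- .sample_time_ms(seq_along(epoch) - 1L, fs_hz)
  pick <- function(lo, hi, what) {
    w <- which(t_ms >= lo & t_ms <= hi)
    i <- w[if (what == "min") which.min(epoch[w]) else which.max(epoch[w])]
    c(ms = t_ms[i], uv = epoch[i])
  }
  n35 <- pick(25, 40, "min")
  p50 <- pick(40, 60, "max")
  n95 <- pick(85, 115, "min")
  data.frame(n35_ms = n35["ms"], n35_uv = n35["uv"],
             p50_ms = p50["ms"], p50_uv = p50["uv"],
             n95_ms = n95["ms"], n95_uv = n95["uv"],
             amp_p50_n35 = abs(p50["uv"] - n35["uv"]),
             amp_n95_p50 = abs(n95["uv"] - p50["uv"]),
             row.names = NULL)
}
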