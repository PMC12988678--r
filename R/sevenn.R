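#' Fourier-domain resampling to a new rate
#'
#' Band-limited sinc interpolation by spectral truncation/extension: the
#' FFT of the input is mapped onto the output length and inverted, scaled
#' by `n_out / n_in`. Equivalent to classic FFT resampling of a
#' periodically extended signal.
#'
#' @param x numeric input.
#' @param n_out output length.
#' @return numeric vector of length `n_out`.
#' @export
fourier_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(as.numeric(x))
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- min(n_in, n_out) %/% 2L
  Y[1] <- X[1]
  if (half >= 1L) {
    Y[2:(half + 1L)] <- X[2:(half + 1L)]
    Y[(n_out - half + 1L):n_out] <- X[(n_in - half + 1L):n_in]
  }
  ## split the shared Nyquist bin when the smaller length is even
  if (min(n_in, n_out) %% 2L == 0L) {
    nyq <- X[half + 1L]
    if (n_out < n_in) {
      Y[half + 1L] <- nyq + X[n_in - half + 1L]
    } else if (n_out > n_in) {
      Y[half + 1L] <- nyq / 2
      Y[n_out - half + 1L] <- nyq / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Prepare a native PERG trace for the 7N metric
#'
#' Resamples the native 1700-Hz trace to 2839 Hz by Fourier-domain rate
#' conversion, zero-pads the end to exactly 512 samples, and min-max
#' normalizes the padded sequence onto `[-2, +2]` (the order follows the
#' metric's published pipeline; see `normalize_before_pad` to apply the
#' normalization to the unpadded trace instead).
#'
#' @param samples native µV samples (non-constant).
#' @param fs_native_hz native rate (default 1700).
#' @param fs_target_hz target rate (default 2839).
#' @param n_out padded length (default 512).
#' @param normalize_before_pad if `TRUE`, normalize before zero-padding.
#' @return numeric vector of length 512 with values in `[-2, 2]`.
#' @export
preprocess_7n <- function(samples, fs_native_hz = 1700,
                          fs_target_hz = 2839, n_out = 512L,
                          normalize_before_pad = FALSE) {
  if (diff(range(samples)) == 0)
    stop("constant trace: min-max normalization undefined")
  n_res <- round(length(samples) * fs_target_hz / fs_native_hz)
  if (n_res > n_out)
    stop("resampled length ", n_res, " exceeds target length ", n_out)
  y <- fourier_resample(as.numeric(samples), n_res)
  minmax <- function(v) (v - min(v)) / (max(v) - min(v)) * 4 - 2
  if (normalize_before_pad) {
    c(minmax(y), rep(0, n_out - n_res))
  } else {
    minmax(c(y, rep(0, n_out - n_res)))
  }
}

#' The 7N metric: db8 level-7 detail energy percentage
#'
#' Applies a seven-level Daubechies-8 decomposition (periodic extension)
#' to a 512-sample prepared trace, isolates the four level-7 detail
#' coefficients, and returns the percentage of their combined energy
#' carried by the third: `7N = 100 * D7-3^2 / sum_i D7-i^2`.
#'
#' @param input 512-sample vector from [preprocess_7n()].
#' @return list with `e` (the four level-7 detail energies) and `seven_n`
#'   (percent, in `[0, 100]`).
#' @export
compute_7n <- function(input) {
  stopifnot(length(input) == 512L)
  dec <- perg_dwt(input, "db8", 7L)
  d7 <- dec$D[[7L]]
  e <- d7^2
  if (sum(e) == 0) stop("all level-7 detail energies are zero")
  list(e = e, seven_n = 100 * e[3] / sum(e))
}

#' 7N for a raw native-rate recording
#'
#' Convenience wrapper: [preprocess_7n()] then [compute_7n()].
#'
#' @inheritParams preprocess_7n
#' @return the `seven_n` percentage.
#' @export
seven_n <- function(samples, fs_native_hz = 1700) {
  compute_7n(preprocess_7n(samples, fs_native_hz))$seven_n
}
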