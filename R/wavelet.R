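## Orthonormal scaling (low-pass) filter taps. sym2 is identical to db2 at
## two vanishing moments; db8 has eight. Taps are the published double-
## precision constants; the high-pass filter follows by quadrature mirror.
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  sym2 = c(-0.12940952255092145, 0.22414386804185735,
           0.836516303737469, 0.48296291314469025),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401)
)

wavelet_filter <- function(wavelet) {
  h <- .wavelet_filters[[match.arg(wavelet, names(.wavelet_filters))]]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L))     # g[m] = (-1)^(m+1) h[L-1-m], 0-based
  list(lo = h, hi = g, length = L)
}

## One analysis step with periodic ("per") extension on an even-length x:
## a[k] = sum_m h[m] x[(2k + L/2 - m) mod n], k = 0..n/2-1 (0-based).
## The L/2 phase keeps coefficient k time-aligned with samples ~[2k, 2k+1].
.dwt_step <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  L <- filt$length
  idx <- outer(2L * (seq_len(n2) - 1L) + L %/% 2L, seq_len(L) - 1L, `-`) %% n
  xm <- matrix(x[idx + 1L], nrow = n2)
  list(a = drop(xm %*% filt$lo), d = drop(xm %*% filt$hi))
}

## Adjoint (= inverse, by orthogonality) of .dwt_step.
.idwt_step <- function(a, d, filt) {
  n2 <- length(a)
  n <- 2L * n2
  L <- filt$length
  x <- numeric(n)
  for (k in seq_len(n2)) {
    pos <- (2L * (k - 1L) + L %/% 2L - (seq_len(L) - 1L)) %% n + 1L
    contrib <- a[k] * filt$lo + d[k] * filt$hi
    for (j in seq_len(L)) x[pos[j]] <- x[pos[j]] + contrib[j]
  }
  x
}

#' Dyadic discrete wavelet transform with periodic extension
#'
#' Decomposes a power-of-two length trace into approximation (`A`) and
#' detail (`D`) coefficients down to `levels`, using the periodic
#' ("per") extension mode. The transform is orthonormal: energy is
#' conserved (Parseval) and [perg_idwt()] inverts it exactly.
#'
#' @param x numeric trace whose length is a power of two (e.g. 256).
#' @param wavelet one of `"sym2"`, `"haar"`, `"db8"`.
#' @param levels decomposition depth `J`; requires `length(x) >= 2^J`.
#' @return an object of class `perg_dwt`: a list with `wavelet`, `levels`,
#'   `n`, the final approximation `A` (length `n / 2^J`) and a list `D`
#'   of detail vectors `D[[j]]` for levels `j = 1..J` (length `n / 2^j`).
#' @examples
#' x <- sin(2 * pi * 7 * seq(0, 0.15, length.out = 256))
#' dec <- perg_dwt(x, "sym2", 6)
#' lengths(dec$D)
#' @export
perg_dwt <- function(x, wavelet = c("sym2", "haar", "db8"), levels) {
  wavelet <- match.arg(wavelet)
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("trace length must be a power of two, got ", n)
  if (2L^levels > n)
    stop("levels = ", levels, " too deep for a trace of length ", n)
  filt <- wavelet_filter(wavelet)
  D <- vector("list", levels)
  a <- as.numeric(x)
  for (j in seq_len(levels)) {
    st <- .dwt_step(a, filt)
    D[[j]] <- st$d
    a <- st$a
  }
  structure(list(wavelet = wavelet, levels = levels, n = n, A = a, D = D),
            class = "perg_dwt")
}

#' Inverse dyadic wavelet transform
#'
#' @param dec a `perg_dwt` object.
#' @return the reconstructed trace of length `dec$n`.
#' @export
perg_idwt <- function(dec) {
  stopifnot(inherits(dec, "perg_dwt"))
  filt <- wavelet_filter(dec$wavelet)
  a <- dec$A
  for (j in rev(seq_len(dec$levels))) a <- .idwt_step(a, dec$D[[j]], filt)
  a
}

#' @export
print.perg_dwt <- function(x, ...) {
  cat("Dyadic DWT (", x$wavelet, ", periodic), ", x$levels,
      " levels on n = ", x$n, "\n", sep = "")
  cat("  A", x$levels, ": ", length(x$A), " coefficients; D sizes: ",
      paste(rev(lengths(x$D)), collapse = " "), " (D",
      x$levels, "..D1)\n", sep = "")
  invisible(x)
}

#' Energy of a single wavelet coefficient
#'
#' The energy index of a coefficient is its square (in µV² for a µV trace).
#'
#' @param dec a `perg_dwt` object.
#' @param level decomposition level `j`.
#' @param band `"detail"` or `"approximation"` (approximation only exists
#'   at the final level).
#' @param position 1-based position `k` along the level, left to right in
#'   time.
#' @return the squared coefficient value.
#' @export
coefficient_energy <- function(dec, level, band = c("detail", "approximation"),
                               position) {
  band <- match.arg(band)
  v <- if (band == "approximation") {
    if (level != dec$levels)
      stop("approximation coefficients are only retained at the final level")
    dec$A
  } else {
    if (level < 1L || level > dec$levels) stop("no detail level ", level)
    dec$D[[level]]
  }
  if (position < 1L || position > length(v))
    stop("position ", position, " out of range for level ", level,
         " (", length(v), " coefficients)")
  v[position]^2
}

#' Nominal time and frequency window of a dyadic coefficient
#'
#' Labels coefficient `k` of level `j` with its nominal time window (ms)
#' and frequency band (Hz) on the canonical PERG grid: a 150-ms epoch of
#' 256 samples nominally at 1700 Hz. Edges are rounded half-to-even to
#' integers, which reproduces the conventional printed windows
#' (e.g. level-6 detail position 2 spans 38-75 ms and 13-27 Hz).
#'
#' @param level level `j`.
#' @param position 1-based position `k`; must satisfy `k <= n / 2^j`.
#' @param band `"detail"` or `"approximation"`.
#' @param fs_hz nominal sampling rate (default 1700).
#' @param epoch_ms nominal epoch duration (default 150).
#' @param n trace length (default 256).
#' @return list with `t_ms = c(lo, hi)` and `f_hz = c(lo, hi)`, integers.
#' @export
nominal_window <- function(level, position, band = c("detail", "approximation"),
                           fs_hz = 1700, epoch_ms = 150, n = 256) {
  band <- match.arg(band)
  width <- n / 2^level
  if (position < 1 || position > width)
    stop("position ", position, " invalid at level ", level, " for n = ", n)
  t_lo <- (position - 1) * epoch_ms * 2^level / n
  t_hi <- position * epoch_ms * 2^level / n
  f <- if (band == "detail") c(fs_hz / 2^(level + 1), fs_hz / 2^level)
       else c(0, fs_hz / 2^(level + 1))
  list(t_ms = round(c(t_lo, t_hi)), f_hz = round(f))
}

## Index address book for the retained feature sets.
.sym2_addresses <- list(
  `sym2-D5-2` = list(level = 5L, band = "detail", position = 2L),
  `sym2-D6-2` = list(level = 6L, band = "detail", position = 2L),
  `sym2-D6-3` = list(level = 6L, band = "detail", position = 3L),
  `sym2-A6-3` = list(level = 6L, band = "approximation", position = 3L),
  `sym2-A6-4` = list(level = 6L, band = "approximation", position = 4L)
)

.haar_addresses <- list(
  `haar-A7-1` = list(level = 7L, band = "approximation", position = 1L),
  `haar-A7-2` = list(level = 7L, band = "approximation", position = 2L),
  `haar-D7-1` = list(level = 7L, band = "detail", position = 1L),
  `haar-D7-2` = list(level = 7L, band = "detail", position = 2L),
  `haar-D6-2` = list(level = 6L, band = "detail", position = 2L),
  `haar-D5-2` = list(level = 5L, band = "detail", position = 2L),
  `haar-D5-3` = list(level = 5L, band = "detail", position = 3L),
  `haar-D5-4` = list(level = 5L, band = "detail", position = 4L)
)

.energy_set <- function(epoch, wavelet, levels, addresses) {
  dec <- perg_dwt(epoch, wavelet, levels)
  vapply(addresses, function(ad)
    coefficient_energy(dec, ad$level, ad$band, ad$position), numeric(1))
}

#' Symlet-2 energy index set for one analysis epoch
#'
#' Computes the five retained sym2 energies (D5-2, D6-2, D6-3, A6-3, A6-4
#' of a six-level decomposition) plus the two combined features
#' `mean(D6-2, A6-3)` and `mean(D6-3, A6-4)`, each the arithmetic mean of
#' its two constituent energies.
#'
#' @param epoch a 256-sample analysis trace (see [detrend_and_pad()]).
#' @return named numeric vector of seven energies (µV²).
#' @export
sym2_index_set <- function(epoch) {
  e <- .energy_set(epoch, "sym2", 6L, .sym2_addresses)
  c(e,
    `sym2-mean-D62-A63` = unname((e["sym2-D6-2"] + e["sym2-A6-3"]) / 2),
    `sym2-mean-D63-A64` = unname((e["sym2-D6-3"] + e["sym2-A6-4"]) / 2))
}

#' Haar energy index set for one analysis epoch
#'
#' The eight retained Haar energies from a seven-level decomposition:
#' A7-1/2 (0-7 Hz; 0-75 and 75-150 ms), D7-1/2 (7-13 Hz), D6-2
#' (13-27 Hz, 38-75 ms) and D5-2/3/4 (27-53 Hz, 19-75 ms).
#'
#' @inheritParams sym2_index_set
#' @return named numeric vector of eight energies (µV²).
#' @export
haar_index_set <- function(epoch) {
  .energy_set(epoch, "haar", 7L, .haar_addresses)
}

#' Rank dyadic indices by mean energy over a set of traces
#'
#' Ranks retained coefficient addresses (details D4 and deeper, plus the
#' final approximation level; D1-D3 lie above the 1-100 Hz analog band and
#' are excluded, and non-final approximations are redundant) by their mean
#' energy across the supplied traces. This is the selection step used to
#' pick a compact Haar representation from healthy-volunteer recordings.
#'
#' @param traces list of equal-length power-of-two traces.
#' @param wavelet mother wavelet.
#' @param levels decomposition depth.
#' @param top_k number of labels to return (default 10).
#' @return data.frame with columns `label`, `level`, `band`, `position`,
#'   `mean_energy`, ordered by decreasing mean energy; ties broken by
#'   deeper level first, then earlier position.
#' @export
rank_indices_by_mean_energy <- function(traces, wavelet = "haar",
                                        levels = 7L, top_k = 10L) {
  if (length(traces) == 0L) stop("no traces supplied")
  decs <- lapply(traces, perg_dwt, wavelet = wavelet, levels = levels)
  rows <- list()
  for (j in seq(4L, levels)) {
    npos <- length(decs[[1]]$D[[j]])
    for (k in seq_len(npos)) {
      e <- mean(vapply(decs, function(d) d$D[[j]][k]^2, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s-D%d-%d", wavelet, j, k),
        level = j, band = "detail", position = k, mean_energy = e)
    }
  }
  for (k in seq_along(decs[[1]]$A)) {
    e <- mean(vapply(decs, function(d) d$A[k]^2, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%s-A%d-%d", wavelet, levels, k),
      level = levels, band = "approximation", position = k, mean_energy = e)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_energy, -tab$level, tab$position)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Partial reconstruction from a subset of coefficients
#'
#' Zeroes every coefficient except the addressed ones and applies the
#' inverse transform; the result is the portion of the trace carried by
#' those time-frequency cells. By linearity, single-index reconstructions
#' sum to the original trace.
#'
#' @param dec a `perg_dwt` object.
#' @param keep list of addresses, each `list(level=, band=, position=)`;
#'   an empty list yields the zero trace.
#' @return reconstructed trace of length `dec$n`.
#' @export
partial_reconstruction <- function(dec, keep) {
  masked <- dec
  masked$A <- numeric(length(dec$A))
  masked$D <- lapply(dec$D, function(v) numeric(length(v)))
  for (ad in keep) {
    if (identical(ad$band, "approximation")) {
      if (ad$level != dec$levels || ad$position > length(dec$A))
        stop("invalid approximation address A", ad$level, "-", ad$position)
      masked$A[ad$position] <- dec$A[ad$position]
    } else {
      if (ad$level > dec$levels || ad$position > length(dec$D[[ad$level]]))
        stop("invalid detail address D", ad$level, "-", ad$position)
      masked$D[[ad$level]][ad$position] <- dec$D[[ad$level]][ad$position]
    }
  }
  perg_idwt(masked)
}

#' Percent-energy scalogram of a decomposition
#'
#' Expresses each retained coefficient's energy as a percent of the total
#' trace energy. Cells over all detail levels plus the final approximation
#' sum to 100 (Parseval).
#'
#' @param dec a `perg_dwt` object with nonzero total energy.
#' @return object of class `perg_scalogram`: a list of `cells` (data.frame
#'   with `level`, `band`, `position`, `percent`, `t_lo_ms`, `t_hi_ms`,
#'   `f_lo_hz`, `f_hi_hz`) plus `wavelet` and `levels`.
#' @export
scalogram <- function(dec) {
  total <- sum(dec$A^2) + sum(unlist(dec$D)^2)
  if (total <= 0) stop("zero-energy trace has no scalogram")
  rows <- list()
  add_row <- function(level, band, position, energy) {
    w <- nominal_window(level, position, band, n = dec$n)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, band = band, position = position,
      percent = 100 * energy / total,
      t_lo_ms = w$t_ms[1], t_hi_ms = w$t_ms[2],
      f_lo_hz = w$f_hz[1], f_hi_hz = w$f_hz[2])
  }
  for (j in seq_len(dec$levels))
    for (k in seq_along(dec$D[[j]])) add_row(j, "detail", k, dec$D[[j]][k]^2)
  for (k in seq_along(dec$A))
    add_row(dec$levels, "approximation", k, dec$A[k]^2)
  structure(list(cells = do.call(rbind, rows), wavelet = dec$wavelet,
                 levels = dec$levels), class = "perg_scalogram")
}

#' @export
print.perg_scalogram <- function(x, ...) {
  cat("Percent-energy scalogram (", x$wavelet, ", ", x$levels,
      " levels), ", nrow(x$cells), " cells\n", sep = "")
  top <- x$cells[order(-x$cells$percent), ][1:5, ]
  cat("  top cells:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %s%d-%d: %.1f%% (%d-%d ms, %d-%d Hz)\n",
                ifelse(top$band[i] == "detail", "D", "A"), top$level[i],
                top$position[i], top$percent[i], top$t_lo_ms[i],
                top$t_hi_ms[i], top$f_lo_hz[i], top$f_hi_hz[i]))
  invisible(x)
}

#' Plot a percent-energy scalogram
#'
#' Renders the dyadic grid as an image, one row per retained band (details
#' D4..DJ and the final approximation split along time), cell shade
#' proportional to percent of total energy.
#'
#' @param x a `perg_scalogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.perg_scalogram <- function(x, ...) {
  cells <- x$cells[x$cells$level >= 4 | x$cells$band == "approximation", ]
  bands <- unique(cells[, c("level", "band")])
  bands <- bands[order(bands$band == "detail", bands$level), ]
  tgrid <- sort(unique(c(cells$t_lo_ms, cells$t_hi_ms)))
  z <- matrix(0, nrow = length(tgrid) - 1, ncol = nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- cells$level == bands$level[b] & cells$band == bands$band[b]
    for (i in which(sel)) {
      span <- tgrid[-length(tgrid)] >= cells$t_lo_ms[i] &
        tgrid[-1] <= cells$t_hi_ms[i]
      z[span, b] <- cells$percent[i]
    }
  }
  graphics::image(x = tgrid, y = seq_len(nrow(bands)), z = z,
                  xlab = "time (ms)", ylab = "band",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(bands)),
                 labels = sprintf("%s%d",
                                  ifelse(bands$band == "detail", "D", "A"),
                                  bands$level), las = 1)
  invisible(x)
}

#' Fraction of total trace energy captured by selected indices
#'
#' @param epoch analysis trace (power-of-two length, nonzero energy).
#' @param addresses list of `list(level=, band=, position=)` addresses.
#' @param wavelet,levels decomposition settings (defaults match the
#'   retained Haar set).
#' @return percent of total energy, in `[0, 100]`.
#' @export
energy_retained_fraction <- function(epoch, addresses = .haar_addresses,
                                     wavelet = "haar", levels = 7L) {
  dec <- perg_dwt(epoch, wavelet, levels)
  total <- sum(dec$A^2) + sum(unlist(dec$D)^2)
  if (total <= 0) stop("zero-energy trace")
  kept <- sum(vapply(addresses, function(ad)
    coefficient_energy(dec, ad$level, ad$band, ad$position), numeric(1)))
  100 * kept / total
}

#' Retained Haar index addresses
#'
#' The eight Haar cells used throughout: A7-1/2, D7-1/2, D6-2, D5-2/3/4.
#' @return named list of address lists.
#' @export
haar_retained_addresses <- function() .haar_addresses
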