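#' Dual-regime analysis frequency grid
#'
#' Constructs the frequency axis used throughout the package: a low range
#' analysed with frequency-adaptive Hanning windows and a high range analysed
#' with fixed-length Slepian multitapers. The default grid has 43 bins:
#' 2--29 Hz in 1-Hz steps and 30--100 Hz in 5-Hz steps.
#'
#' @param low Numeric vector of low-regime frequencies (Hz).
#' @param high Numeric vector of high-regime (multitaper) frequencies (Hz).
#' @return An object of class \code{ers_grid}: a list with \code{freq}
#'   (ordered frequencies in Hz) and \code{regime} (\code{"hanning"} or
#'   \code{"multitaper"} per bin).
#' @examples
#' g <- frequency_grid()
#' length(g$freq)  # 43
#' @export
frequency_grid <- function(low = seq(2, 29, by = 1), high = seq(30, 100, by = 5)) {
  freq <- c(low, high)
  if (length(freq) < 1L || any(diff(freq) <= 0))
    stop("frequencies must be strictly increasing")
  structure(list(freq = freq,
                 regime = c(rep("hanning", length(low)),
                            rep("multitaper", length(high)))),
            class = "ers_grid")
}

#' @export
print.ers_grid <- function(x, ...) {
  cat("<ers_grid> ", length(x$freq), " bins: ",
      sum(x$regime == "hanning"), " hanning (",
      min(x$freq[x$regime == "hanning"]), "-",
      max(x$freq[x$regime == "hanning"]), " Hz), ",
      sum(x$regime == "multitaper"), " multitaper (",
      min(x$freq[x$regime == "multitaper"]), "-",
      max(x$freq[x$regime == "multitaper"]), " Hz)\n", sep = "")
  invisible(x)
}

#' Analysis window length for a grid frequency
#'
#' Low-regime frequencies use a window of \code{n_cycles} cycles of the
#' frequency (e.g. 500 ms at 10 Hz for 5 cycles); multitaper frequencies use
#' a fixed window (400 ms by default).
#'
#' @param frequency Frequency in Hz; must be a bin of \code{grid}.
#' @param grid An \code{\link{frequency_grid}} object.
#' @param n_cycles Cycles per window in the low regime.
#' @param high_window Fixed window length (s) in the multitaper regime.
#' @return Window length(s) in seconds.
#' @examples
#' window_length(10)  # 0.5
#' window_length(50)  # 0.4
#' @export
window_length <- function(frequency, grid = frequency_grid(), n_cycles = 5,
                          high_window = 0.4) {
  i <- match(frequency, grid$freq)
  if (anyNA(i)) stop("frequency not in grid: ",
                     paste(frequency[is.na(i)], collapse = ", "))
  ifelse(grid$regime[i] == "hanning", n_cycles / frequency, high_window)
}

#' Multitaper spectral half-bandwidth
#'
#' Half-bandwidth (Hz) of spectral smoothing obtained when averaging over
#' \code{n_tapers} Slepian tapers on a window of length \code{window} seconds:
#' \code{(n_tapers + 1) / (2 * window)}. Seven tapers on a 400-ms window give
#' +/- 10 Hz.
#'
#' @param n_tapers Number of tapers kept (>= 1).
#' @param window Window length in seconds (> 0).
#' @return Half-bandwidth in Hz.
#' @examples
#' multitaper_halfbandwidth(7, 0.4)  # 10
#' @export
multitaper_halfbandwidth <- function(n_tapers, window) {
  if (any(n_tapers < 1) || any(window <= 0))
    stop("n_tapers must be >= 1 and window > 0")
  (n_tapers + 1) / (2 * window)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first \code{k} DPSS tapers of length \code{n} with
#' half-bandwidth parameter \code{w} (cycles per sample) via the symmetric
#' tridiagonal formulation. Tapers are unit-energy and ordered by spectral
#' concentration. Sign convention: symmetric tapers have positive mean,
#' antisymmetric tapers a positive initial slope.
#'
#' @param n Taper length in samples.
#' @param w Half-bandwidth in cycles per sample (0 < w < 0.5).
#' @param k Number of tapers to return.
#' @return An \code{n x k} matrix, one taper per column.
#' @export
dpss_tapers <- function(n, w, k) {
  stopifnot(n >= 2, w > 0, w < 0.5, k >= 1, k <= n)
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  kk <- seq_len(n - 1)
  e <- kk * (n - kk) / 2
  # dense symmetric tridiagonal eigen-decomposition; n is a few hundred here
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2 == 1) {            # symmetric order (0, 2, ...)
      if (sum(v) < 0) v <- -v
    } else if (v[2] - v[1] < 0) v <- -v
    V[, j] <- v
  }
  V
}

# package-level cache for taper/weight matrices (keyed by parameter string)
.ers_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, fn) {
  if (!is.null(.ers_cache[[key]])) return(.ers_cache[[key]])
  val <- fn()
  assign(key, val, envir = .ers_cache)
  val
}

# odd sample count for a window of `len` seconds at sampling rate fs
.odd_len <- function(len, fs) 2L * as.integer(floor(len * fs / 2)) + 1L

# complex demodulation weights for one low-regime frequency: Hanning taper
# (unit energy) times exp(-2*pi*i*f*t), t centred on the window
.hanning_weights <- function(f, fs, n_cycles) {
  L <- .odd_len(n_cycles / f, fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  w <- w / sqrt(sum(w^2))
  t <- (seq_len(L) - (L + 1) / 2) / fs
  w * exp(-2i * pi * f * t)
}

# per-taper complex weights for all multitaper frequencies: list with
# L (samples) and a complex L x (n_freq * n_tapers) matrix, taper index
# fastest within frequency
.multitaper_weights <- function(freqs, fs, high_window, n_tapers) {
  L <- .odd_len(high_window, fs)
  hb <- multitaper_halfbandwidth(n_tapers, high_window)
  V <- dpss_tapers(L, hb / fs, n_tapers)
  t <- (seq_len(L) - (L + 1) / 2) / fs
  U <- matrix(0i, L, length(freqs) * n_tapers)
  for (j in seq_along(freqs)) {
    ph <- exp(-2i * pi * freqs[j] * t)
    U[, (j - 1L) * n_tapers + seq_len(n_tapers)] <- V * ph
  }
  list(L = L, U = U)
}
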