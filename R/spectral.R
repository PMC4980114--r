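#' Dual-regime sliding-window time-frequency decomposition
#'
#' Fourier power on a sliding time grid (10-ms steps by default). Low-regime
#' frequencies use a Hanning taper with a window of 5 cycles of the
#' frequency; high-regime frequencies use 7 orthogonal Slepian tapers on a
#' fixed 400-ms window (spectral smoothing about +/- 10 Hz), power averaged
#' over tapers. Power is read out at the exact grid frequency by a
#' taper-windowed DFT (no bin interpolation). Windows are centred on the
#' output bin with odd sample counts; bins whose full window does not fit in
#' the epoch are masked invalid (NA).
#'
#' @param epochs An \code{\link{epoch_set}}.
#' @param grid A \code{\link{frequency_grid}}.
#' @param time_step Output time step in seconds (must be a multiple of the
#'   sample interval).
#' @param t_range Optional c(lo, hi) restriction of the output time axis (s).
#' @param n_cycles Cycles per window in the Hanning regime (5 by default;
#'   4 gives the shortened-window preset).
#' @param high_window Multitaper window length in seconds (0.4 by default;
#'   0.2 gives the shortened preset).
#' @param n_tapers Number of Slepian tapers kept.
#' @return An object of class \code{ers_tfr}: \code{power} (trial x
#'   frequency x time, raw), \code{freqs}, \code{times}, \code{valid}
#'   (frequency x time logical mask), \code{normalization} flag, lock and
#'   linked events.
#' @export
tfr_transform <- function(epochs, grid = frequency_grid(), time_step = 0.01,
                          t_range = NULL, n_cycles = 5, high_window = 0.4,
                          n_tapers = 7) {
  X <- epochs$data
  fs <- epochs$fs
  times <- epochs$times
  nsamp <- ncol(X)
  stride <- time_step * fs
  if (abs(stride - round(stride)) > 1e-9)
    stop("time_step must be a multiple of the sample interval")
  stride <- as.integer(round(stride))
  k0 <- ceiling(round(times[1] / time_step, 9))
  k1 <- floor(round(times[nsamp] / time_step, 9))
  tc <- (k0:k1) * time_step
  if (!is.null(t_range)) tc <- tc[tc >= t_range[1] - 1e-9 &
                                    tc <= t_range[2] + 1e-9]
  s_idx <- as.integer(round((tc - times[1]) * fs)) + 1L
  ntrial <- nrow(X)
  nf <- length(grid$freq)
  nt <- length(tc)
  pow <- array(NA_real_, c(ntrial, nf, nt))
  valid <- matrix(FALSE, nf, nt)
  # longest window must fit somewhere; otherwise mask (not fail) if >= 50%
  # of the grid remains valid -- checked at the end

  low <- which(grid$regime == "hanning")
  for (j in low) {
    f <- grid$freq[j]
    key <- sprintf("hann_%g_%g_%g", f, fs, n_cycles)
    u <- .cache_get(key, function() .hanning_weights(f, fs, n_cycles))
    L <- length(u)
    h <- (L - 1L) %/% 2L
    vc <- which(s_idx - h >= 1L & s_idx + h <= nsamp)
    if (!length(vc)) next
    valid[j, vc] <- TRUE
    chunk <- 48L
    b0 <- 1L
    while (b0 <= length(vc)) {
      cs <- vc[b0:min(b0 + chunk - 1L, length(vc))]
      k <- length(cs)
      wkey <- sprintf("%s_blk%d_%d", key, k, stride)
      W <- .cache_get(wkey, function() .block_weights(u, k, stride))
      a0 <- s_idx[cs[1]] - h
      P <- X[, a0:(a0 + nrow(W) - 1L), drop = FALSE] %*% W
      odd <- seq(1L, 2L * k, by = 2L)
      pow[, j, cs] <- P[, odd, drop = FALSE]^2 + P[, odd + 1L, drop = FALSE]^2
      b0 <- b0 + chunk
    }
  }

  hi <- which(grid$regime == "multitaper")
  if (length(hi)) {
    fh <- grid$freq[hi]
    key <- sprintf("mt_%s_%g_%g_%d", paste(range(fh), collapse = "-"), fs,
                   high_window, n_tapers)
    mt <- .cache_get(key, function()
      .multitaper_weights(fh, fs, high_window, n_tapers))
    L <- mt$L
    h <- (L - 1L) %/% 2L
    Wh <- .cache_get(paste0(key, "_re"), function()
      cbind(Re(mt$U), Im(mt$U)))
    ncolU <- ncol(mt$U)
    M <- .cache_get(paste0(key, "_avg"), function()
      kronecker(diag(length(fh)), matrix(1 / n_tapers, n_tapers, 1)))
    vc <- which(s_idx - h >= 1L & s_idx + h <= nsamp)
    valid[hi, vc] <- TRUE
    for (c in vc) {
      P <- X[, (s_idx[c] - h):(s_idx[c] + h), drop = FALSE] %*% Wh
      Psq <- P[, seq_len(ncolU), drop = FALSE]^2 +
        P[, ncolU + seq_len(ncolU), drop = FALSE]^2
      pow[, hi, c] <- Psq %*% M
    }
  }

  if (mean(valid) < 0.5)
    stop("epoch too short: less than 50% of the time-frequency grid is valid")
  structure(list(power = pow, freqs = grid$freq, times = tc, valid = valid,
                 trial_valid = NULL, normalization = "raw",
                 baseline_window = NULL, lock = epochs$lock, fs = fs,
                 events = epochs$events),
            class = "ers_tfr")
}

# stacked sliding-window weight matrix: k shifted copies (stride samples
# apart) of Re/Im of the complex demodulation weights, as columns
.block_weights <- function(u, k, stride) {
  L <- length(u)
  W <- matrix(0, L + stride * (k - 1L), 2L * k)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * stride + seq_len(L)
    W[rows, 2L * j - 1L] <- Re(u)
    W[rows, 2L * j] <- Im(u)
  }
  W
}

#' @export
print.ers_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat("<ers_tfr> ", d[1], " trials x ", d[2], " freqs (",
      min(x$freqs), "-", max(x$freqs), " Hz) x ", d[3], " times (",
      sprintf("%.2f", x$times[1]), "..", sprintf("%.2f", x$times[d[3]]),
      " s), ", x$normalization, " power, ", x$lock, "-locked\n", sep = "")
  invisible(x)
}

#' Relative-power baseline normalization
#'
#' Divides each trial's power, per frequency, by the mean power over the
#' pre-stimulus baseline window (-0.5..0 s by default), yielding
#' "proportional power change". Only valid baseline bins contribute; for
#' frequencies whose analysis window never fits inside the baseline interval
#' (2 Hz on a -1..+3 s epoch), the earliest valid bins spanning the same
#' duration are used instead when \code{fallback = TRUE}.
#'
#' @param tfr A raw \code{ers_tfr}.
#' @param window Baseline window c(lo, hi) in seconds, inclusive.
#' @param fallback Use earliest valid bins for frequencies with no valid
#'   baseline bin (otherwise an error).
#' @return The normalized \code{ers_tfr} (\code{normalization = "relative"}).
#' @export
baseline_normalize <- function(tfr, window = c(-0.5, 0), fallback = TRUE) {
  stopifnot(inherits(tfr, "ers_tfr"))
  if (tfr$normalization != "raw") stop("tfr must hold raw power")
  nf <- dim(tfr$power)[2]
  ntrial <- dim(tfr$power)[1]
  ntime <- dim(tfr$power)[3]
  step <- tfr$times[2] - tfr$times[1]
  nb <- as.integer(round((window[2] - window[1]) / step)) + 1L
  denom <- matrix(NA_real_, ntrial, nf)
  for (f in seq_len(nf)) {
    inwin <- tfr$valid[f, ] & tfr$times >= window[1] - 1e-9 &
      tfr$times <= window[2] + 1e-9
    bins <- which(inwin)
    if (!length(bins)) {
      if (!fallback)
        stop("no valid baseline bins for ", tfr$freqs[f], " Hz")
      bins <- utils::head(which(tfr$valid[f, ]), nb)
      if (!length(bins))
        stop("frequency ", tfr$freqs[f], " Hz has no valid bins")
    }
    denom[, f] <- rowMeans(tfr$power[, f, bins, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(denom[, f])) || any(denom[, f] <= 0))
      stop("zero or undefined baseline power at ", tfr$freqs[f], " Hz")
  }
  # broadcast trial x freq baselines over the time axis in one step
  tfr$power <- array(as.vector(tfr$power) / rep(as.vector(denom), ntime),
                     dim(tfr$power))
  tfr$normalization <- "relative"
  tfr$baseline_window <- window
  tfr
}

#' Log-transform raw power
#'
#' Natural log of raw power, the no-baseline control used to rule out
#' pre-stimulus condition differences.
#'
#' @param tfr A raw, strictly positive \code{ers_tfr}.
#' @return The log-power \code{ers_tfr} (\code{normalization = "log"}).
#' @export
log_power <- function(tfr) {
  stopifnot(inherits(tfr, "ers_tfr"))
  if (tfr$normalization != "raw") stop("tfr must hold raw power")
  if (any(tfr$power[!is.na(tfr$power)] <= 0))
    stop("power must be strictly positive")
  tfr$power <- log(tfr$power)
  tfr$normalization <- "log"
  tfr
}

#' Band-averaged power time course
#'
#' Mean power over the frequency bins of a band, per trial, plus the mean
#' and standard error across the selected trials. Time bins that are invalid
#' for any band frequency are NA.
#'
#' @param tfr An \code{ers_tfr}.
#' @param band c(lo, hi) band limits in Hz (inclusive).
#' @param trials Optional trial indices (default: all).
#' @return A list with \code{times}, \code{mean}, \code{sem} and
#'   \code{per_trial} (trials x time matrix).
#' @export
band_timecourse <- function(tfr, band, trials = NULL) {
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(rows)) stop("band does not intersect the frequency grid")
  if (is.null(trials)) trials <- seq_len(dim(tfr$power)[1])
  acc <- tfr$power[trials, rows[1], , drop = TRUE]
  if (length(trials) == 1L) acc <- matrix(acc, nrow = 1L)
  if (length(rows) > 1L) for (r in rows[-1]) {
    v <- tfr$power[trials, r, , drop = TRUE]
    if (length(trials) == 1L) v <- matrix(v, nrow = 1L)
    acc <- acc + v
  }
  per_trial <- acc / length(rows)
  bad <- !apply(tfr$valid[rows, , drop = FALSE], 2, all)
  per_trial[, bad] <- NA_real_
  n <- length(trials)
  list(times = tfr$times, mean = colMeans(per_trial),
       sem = apply(per_trial, 2, stats::sd) / sqrt(n),
       per_trial = per_trial)
}

#' Mean power over a time-frequency window or mask
#'
#' Per-trial mean of power over the bins selected by a frequency/time window
#' (or an explicit frequency x time mask), restricted to valid bins.
#'
#' @param tfr An \code{ers_tfr}.
#' @param freq_range c(lo, hi) in Hz (ignored when \code{mask} given).
#' @param time_range c(lo, hi) in s (ignored when \code{mask} given).
#' @param trials Optional trial indices (default: all).
#' @param mask Optional logical frequency x time matrix.
#' @return Numeric vector of per-trial means.
#' @export
cluster_mean_power <- function(tfr, freq_range = NULL, time_range = NULL,
                               trials = NULL, mask = NULL) {
  if (is.null(mask)) {
    if (is.null(freq_range) || is.null(time_range))
      stop("give either a mask or freq_range + time_range")
    mask <- outer(tfr$freqs >= freq_range[1] & tfr$freqs <= freq_range[2],
                  tfr$times >= time_range[1] - 1e-9 &
                    tfr$times <= time_range[2] + 1e-9, `&`)
  }
  mask <- mask & tfr$valid
  if (!any(mask)) stop("empty mask")
  if (is.null(trials)) trials <- seq_len(dim(tfr$power)[1])
  vapply(trials, function(i) {
    sl <- tfr$power[i, , ]
    m <- mask
    if (!is.null(tfr$trial_valid)) m <- m & rep(tfr$trial_valid[i, ],
                                                each = nrow(mask))
    mean(sl[m], na.rm = TRUE)
  }, numeric(1))
}
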