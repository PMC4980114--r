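#' Automated joint amplitude/gradient artifact rejection
#'
#' Implements the automated rejection rule: pooling all time points of all
#' trials (one channel, one phase), two thresholds are computed as
#' \code{median + 3 * IQR} of the absolute amplitude and of the absolute
#' gradient (first difference). A trial is rejected if and only if at least
#' one time point exceeds \emph{both} thresholds simultaneously. Thresholds
#' depend only on the pooled sample, so the rule is equivariant under trial
#' reordering.
#'
#' @param epochs An \code{\link{epoch_set}} with at least 2 trials.
#' @return A list: \code{clean} (the retained \code{epoch_set}),
#'   \code{rejected} (logical mask over input trials) and
#'   \code{thresholds} (amplitude and gradient thresholds).
#' @export
reject_artifacts <- function(epochs) {
  x <- epochs$data
  if (is.null(x) || nrow(x) == 0) stop("empty epoch set")
  if (nrow(x) < 2) stop("need at least 2 trials")
  aa <- abs(x)
  gg <- abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  th_a <- stats::median(aa) + 3 * stats::IQR(aa)
  th_g <- stats::median(gg) + 3 * stats::IQR(gg)
  # joint exceedance at the same time point: gradient at column j is the
  # step onto sample j+1, compared against the amplitude at sample j+1
  joint <- aa[, -1, drop = FALSE] > th_a & gg > th_g
  rejected <- rowSums(joint) > 0
  list(clean = epochs[!rejected], rejected = rejected,
       thresholds = c(amplitude = th_a, gradient = th_g))
}

#' Response-lock stimulus-locked epochs
#'
#' Realigns each trial's time axis to the behavioural response: the output
#' sample at time t equals the input sample at (latency + t), with the
#' latency snapped to the nearest sample. Trials whose realigned window
#' falls outside the source epoch, or whose latency is missing, are dropped
#' with a warning.
#'
#' @param epochs A stimulus-locked \code{\link{epoch_set}}.
#' @param latencies Response latencies (s); defaults to the events table's
#'   \code{rt_s} column.
#' @param window Output window (s) relative to the response.
#' @return A response-locked \code{epoch_set}; dropped trial indices are in
#'   attribute \code{"dropped"}.
#' @export
response_lock <- function(epochs, latencies = epochs$events$rt_s,
                          window = c(-1, 0.1)) {
  if (is.null(latencies)) stop("latencies are required")
  stopifnot(length(latencies) == nrow(epochs$data))
  fs <- epochs$fs
  nout <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  t_out <- window[1] + (seq_len(nout) - 1L) / fs
  n <- ncol(epochs$data)
  start <- as.integer(round((latencies + window[1] - epochs$times[1]) * fs)) + 1L
  ok <- !is.na(latencies) & start >= 1L & (start + nout - 1L) <= n
  if (!all(ok))
    warning(sum(!ok), " trial(s) dropped: realigned window outside epoch ",
            "or missing latency")
  if (!any(ok)) stop("no trials with a valid response-locked window")
  keep <- which(ok)
  out <- matrix(NA_real_, length(keep), nout)
  for (i in seq_along(keep))
    out[i, ] <- epochs$data[keep[i], start[keep[i]] + seq_len(nout) - 1L]
  res <- epoch_set(out, t_out, fs, "response",
                   if (!is.null(epochs$events))
                     epochs$events[keep, , drop = FALSE])
  attr(res, "dropped") <- which(!ok)
  res
}

#' Response-lock a time-frequency representation
#'
#' Shifts the 10-ms time grid of a stimulus-locked TFR to response-locked
#' time, snapping each trial's latency to the nearest grid bin. Spectral
#' estimates are not recomputed: bins inherit their stimulus-locked values
#' and validity, which avoids re-windowing edge artifacts. Because trials
#' have different latencies, validity becomes trial-specific; bins outside a
#' trial's valid realigned range are set to NA and recorded in the
#' \code{trial_valid} mask.
#'
#' @param tfr A stimulus-locked \code{ers_tfr} (see
#'   \code{\link{tfr_transform}}).
#' @param latencies Response latencies (s); defaults to the linked events.
#' @param window Output window (s) relative to the response.
#' @return A response-locked \code{ers_tfr} with an additional
#'   \code{trial_valid} matrix (trials x time).
#' @export
response_lock_tfr <- function(tfr, latencies = tfr$events$rt_s,
                              window = c(-1, 0.1)) {
  stopifnot(inherits(tfr, "ers_tfr"), tfr$lock == "stimulus")
  if (is.null(latencies)) stop("latencies are required")
  ntrial <- dim(tfr$power)[1]
  stopifnot(length(latencies) == ntrial)
  step <- tfr$times[2] - tfr$times[1]
  t_out <- seq(window[1], window[2], by = step)
  t_out <- round(t_out / step) * step
  nt <- length(t_out)
  nf <- dim(tfr$power)[2]
  pow <- array(NA_real_, c(ntrial, nf, nt))
  tv <- matrix(FALSE, ntrial, nt)
  valid_out <- matrix(FALSE, nf, nt)
  for (i in seq_len(ntrial)) {
    if (is.na(latencies[i])) next
    src_t <- latencies[i] + t_out
    j <- round((src_t - tfr$times[1]) / step) + 1L
    ok <- j >= 1L & j <= length(tfr$times)
    if (!any(ok)) next
    pow[i, , ok] <- tfr$power[i, , j[ok]]
    tv[i, ok] <- TRUE
    # per-trial frequency validity is inherited; a bin counts as valid for
    # the shared mask only where every frequency was valid at the source
    tv[i, ok] <- tv[i, ok] & apply(tfr$valid[, j[ok], drop = FALSE], 2, all)
  }
  # shared mask: bins valid in at least one trial per frequency (per-trial
  # detail is in trial_valid)
  for (jj in seq_len(nt)) valid_out[, jj] <- any(tv[, jj])
  structure(list(power = pow, freqs = tfr$freqs, times = t_out,
                 valid = valid_out, trial_valid = tv,
                 normalization = tfr$normalization,
                 baseline_window = tfr$baseline_window,
                 lock = "response", fs = tfr$fs, events = tfr$events),
            class = "ers_tfr")
}
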