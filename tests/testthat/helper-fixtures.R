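# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# minimal ers_tfr built directly from a power array (trial x freq x time)
toy_tfr <- function(power, freqs, times, valid = NULL, events = NULL,
                    normalization = "relative", lock = "stimulus") {
  if (is.null(valid)) valid <- matrix(TRUE, dim(power)[2], dim(power)[3])
  structure(list(power = power, freqs = freqs, times = times,
                 valid = valid, trial_valid = NULL,
                 normalization = normalization, baseline_window = NULL,
                 lock = lock, fs = 1000, events = events),
            class = "ers_tfr")
}

# small epoch_set of coloured-noise background trials (no planted effects)
background_epochs <- function(n_trials, seed = 1, fs = 1000,
                              window = c(-1, 3), exponent = 2) {
  set.seed(seed)
  n <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  nfft <- 2^ceiling(log2(n))
  fb <- (seq_len(nfft) - 1) * fs / nfft
  fb <- pmin(fb, fs - fb)
  amp <- ersim:::.bg_amp_spectrum(fb, exponent, list())
  X <- t(ersim:::.spectral_noise(n, n_trials, amp)) * 25
  epoch_set(X, window[1] + (seq_len(n) - 1) / fs, fs, "stimulus")
}

# tiny full TFR grid fitting a short epoch: low frequencies only need short
# windows, so tests that exercise the full 43-bin grid use the real epochs;
# tests of map mechanics use this reduced grid
toy_grid <- function() frequency_grid(low = c(8, 10, 12), high = c(40, 60))

# deterministic small events table
toy_events <- function(n_ar = 6, n_ir = 4, participant = 1) {
  n <- n_ar + n_ir
  data.frame(participant = participant, trial = seq_len(n),
             phase = "retrieval",
             condition = rep(c("AR", "IR"), c(n_ar, n_ir)),
             association = rep(c("blue", "red"), length.out = n),
             block_type = "colour", rt_s = 2,
             old_new = "old", is_artifact = FALSE)
}
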