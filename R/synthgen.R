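#' Configuration for a synthetic associative-recognition iEEG study
#'
#' Bundles all parameters of the simulated experiment: cohort and trial
#' counts, epoch geometry, the 1/f background, the trial-unique
#' time-frequency fingerprints shared between a trial's encoding and
#' retrieval epochs on AR trials, condition-level gamma/alpha band effects,
#' response-latency distributions and the artifact process.
#'
#' Defaults emulate the study conditions the package is designed around:
#' 11 participants; AR/IR/M/CR = 40/40/20/20 trials; 1 kHz sampling of
#' -1..+3 s stimulus-locked epochs; fingerprints planted at 0.5--1 s during
#' encoding and reinstated at 1--1.5 s during AR retrieval; a 50--90 Hz
#' gamma power increase at 0.5--1.3 s for AR and an 8--12 Hz alpha power
#' increase at 1--2 s for IR; AR responses faster than IR (means 1.91 s vs
#' 2.14 s); 12 percent artifact trials.
#'
#' @param n_participants Number of participants.
#' @param n_trials Named counts per retrieval condition (AR, IR, M, CR).
#' @param sampling_rate Sampling rate, Hz.
#' @param epoch_window Stimulus-locked epoch bounds in seconds.
#' @param associations Four association labels (two colours, two scenes).
#' @param noise_exponent Spectral exponent chi of the 1/f^chi background power
#'   spectrum.
#' @param osc_mixture List of background oscillatory components, each
#'   \code{list(band = c(lo, hi), amplitude)}; amplitudes are relative to the
#'   local 1/f amplitude.
#' @param fingerprint List: \code{enc_window}, \code{ret_window} (s),
#'   \code{freq_span} (Hz), \code{amplitude} (total fingerprint RMS relative
#'   to background SD), \code{mixing_weight} (association-shared vs
#'   trial-unique mixing, in [0, 1]) and \code{n_time} (envelope time
#'   resolution).
#' @param gamma_effect List: \code{band}, \code{window}, \code{amplitude}
#'   (burst SD relative to background SD within the band) and
#'   \code{condition}.
#' @param alpha_effect As \code{gamma_effect}, plus \code{ar_amplitude}: a
#'   weaker alpha component on AR trials whose per-trial amplitude is
#'   anti-coupled to the gamma/reinstatement modulator.
#' @param coupling Strength of the shared per-trial modulator linking AR
#'   gamma amplitude, reinstatement fingerprint amplitude and (negatively)
#'   AR alpha amplitude; 0 disables the linkage.
#' @param rt Named list of \code{c(mean, sd)} response-latency moments (s)
#'   per condition.
#' @param rt_shift,rt_max Shift and truncation point (s) of the shifted
#'   log-normal latency distribution.
#' @param artifact_rate Per-trial probability of a planted artifact.
#' @param artifact_scale Artifact amplitude in units of the trace SD.
#' @param base_sd Background trace SD in microvolts.
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return An object of class \code{ers_config} (a validated list).
#' @export
study_config <- function(n_participants = 11,
                         n_trials = c(AR = 40, IR = 40, M = 20, CR = 20),
                         sampling_rate = 1000,
                         epoch_window = c(-1, 3),
                         associations = c("blue", "red", "indoor", "outdoor"),
                         noise_exponent = 2,
                         osc_mixture = list(
                           list(band = c(4, 8), amplitude = 0.3),
                           list(band = c(8, 12), amplitude = 0.25),
                           list(band = c(40, 80), amplitude = 0.2)),
                         fingerprint = list(),
                         gamma_effect = list(),
                         alpha_effect = list(),
                         coupling = 0.5,
                         rt = list(AR = c(1.91, 0.45), IR = c(2.14, 0.45),
                                   M = c(2.30, 0.50), CR = c(1.90, 0.45)),
                         rt_shift = 0.3, rt_max = 5,
                         artifact_rate = 0.12, artifact_scale = 8,
                         base_sd = 25, seed = NULL) {
  fingerprint <- utils::modifyList(list(
    enc_window = c(0.5, 1), ret_window = c(1, 1.5), freq_span = c(2, 100),
    amplitude = 0.45, mixing_weight = 0.3, n_time = 26, contrast = 1.4),
    fingerprint)
  gamma_effect <- utils::modifyList(list(
    band = c(50, 90), window = c(0.5, 1.3), amplitude = 0.9,
    condition = "AR"), gamma_effect)
  alpha_effect <- utils::modifyList(list(
    band = c(8, 12), window = c(1, 2), amplitude = 2.8,
    condition = "IR", ar_amplitude = 0.35), alpha_effect)
  cfg <- structure(list(
    n_participants = n_participants, n_trials = n_trials,
    sampling_rate = sampling_rate, epoch_window = epoch_window,
    associations = associations, noise_exponent = noise_exponent,
    osc_mixture = osc_mixture, fingerprint = fingerprint,
    gamma_effect = gamma_effect, alpha_effect = alpha_effect,
    coupling = coupling, rt = rt, rt_shift = rt_shift, rt_max = rt_max,
    artifact_rate = artifact_rate, artifact_scale = artifact_scale,
    base_sd = base_sd, seed = seed), class = "ers_config")
  validate_config(cfg)
}

#' @rdname study_config
#' @param config An \code{ers_config} object.
#' @export
validate_config <- function(config) {
  with(config, {
    if (n_participants < 1) stop("n_participants must be positive")
    if (!all(c("AR", "IR", "M", "CR") %in% names(n_trials)))
      stop("n_trials must name AR, IR, M and CR")
    if (any(n_trials < 0) || n_trials[["AR"]] < 1)
      stop("trial counts must be non-negative (and AR positive)")
    if (epoch_window[1] >= epoch_window[2]) stop("epoch_window start < end")
    if (anyDuplicated(associations) || length(associations) != 4)
      stop("associations must be 4 unique labels")
    for (w in list(fingerprint$enc_window, fingerprint$ret_window,
                   gamma_effect$window, alpha_effect$window))
      if (w[1] < epoch_window[1] || w[2] > epoch_window[2])
        stop("planted windows must lie within the epoch window")
    if (fingerprint$mixing_weight < 0 || fingerprint$mixing_weight > 1)
      stop("mixing_weight must lie in [0, 1]")
    if (artifact_rate < 0 || artifact_rate > 1)
      stop("artifact_rate must be a probability")
  })
  config
}

# ---- low-level signal building blocks -------------------------------------

# composite amplitude spectrum (one value per FFT bin frequency) of the
# background: 1/f^(chi/2) scaled by (1 + sum of oscillatory band bumps).
# The power law is floored below 1 Hz (hardware high-pass plus spectral
# flattening); without the floor, sub-hertz drift power leaks through the
# taper sidelobes and dominates the high-frequency estimates.
.bg_amp_spectrum <- function(f, exponent, osc, f_floor = 1) {
  amp <- ifelse(f > 0, pmax(f, f_floor)^(-exponent / 2), 0)
  bump <- rep(0, length(f))
  for (o in osc) {
    b <- o$band
    inside <- f >= b[1] & f <= b[2]
    # raised-cosine edges over 20% of the band width
    w <- 0.2 * (b[2] - b[1])
    ramp <- rep(0, length(f))
    ramp[inside] <- 1
    lo <- f >= b[1] - w & f < b[1]
    hi <- f > b[2] & f <= b[2] + w
    ramp[lo] <- 0.5 + 0.5 * cos(pi * (b[1] - f[lo]) / w)
    ramp[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - b[2]) / w)
    bump <- bump + o$amplitude * ramp
  }
  amp * (1 + bump)
}

# spectral synthesis of m coloured-noise traces of n samples: complex
# Gaussian spectrum shaped by `amp` (length nfft), real part of the inverse
# FFT; returns n x m matrix with overall SD 1
.spectral_noise <- function(n, m, amp) {
  nfft <- length(amp)
  Z <- matrix(stats::rnorm(nfft * m), nfft, m) +
    1i * matrix(stats::rnorm(nfft * m), nfft, m)
  X <- Re(stats::mvfft(Z * amp, inverse = TRUE))[seq_len(n), , drop = FALSE]
  X / sqrt(mean(X^2))
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

# band-limited noise bursts: n x m matrix, unit SD within the support,
# zero outside `window` (sample indices), Tukey-ramped edges
.band_bursts <- function(n, m, fs, band, window, ramp_frac = 0.15) {
  len <- window[2] - window[1] + 1L
  nfft <- .next_pow2(len)
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)
  amp <- as.numeric(f >= band[1] & f <= band[2])
  B <- .spectral_noise(len, m, amp)
  B <- sweep(B, 2, sqrt(colMeans(B^2)), "/")
  nr <- max(2L, round(ramp_frac * len))
  taper <- rep(1, len)
  taper[seq_len(nr)] <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = nr))
  taper[len + 1 - seq_len(nr)] <- taper[seq_len(nr)]
  B <- B * taper
  out <- matrix(0, n, m)
  out[window[1]:window[2], ] <- B
  out
}

# linear interpolation basis mapping k knots onto n points
.interp_basis <- function(n, k) {
  if (k == 1) return(matrix(1, n, 1))
  pos <- seq(1, k, length.out = n)
  lo <- pmin(floor(pos), k - 1)
  w <- pos - lo
  B <- matrix(0, n, k)
  B[cbind(seq_len(n), lo)] <- 1 - w
  B[cbind(seq_len(n), lo + 1)] <- w
  B
}

# smooth standard-normal random field on an nf x nt grid (kf x kt knots)
.smooth_field <- function(nf, nt, kf = 7, kt = 4) {
  K <- matrix(stats::rnorm(kf * kt), kf, kt)
  G <- .interp_basis(nf, kf) %*% K %*% t(.interp_basis(nt, kt))
  G / stats::sd(G)
}

#' Generate a trial time-frequency fingerprint
#'
#' A fingerprint is a smooth positive frequency x time envelope on the
#' analysis frequency grid, mixing an association-shared component with a
#' trial-unique component: with mixing weight w the field is
#' \code{w * shared + (1 - w) * unique}. Same-association trials are
#' therefore more similar to each other than cross-association trials, but
#' less similar than a trial is to itself.
#'
#' @param association Association label (must index \code{assoc_fields}).
#' @param assoc_fields Named list of association-shared fields (matrices of
#'   the same dimension as the output); generated internally per participant
#'   by \code{\link{generate_dataset}}. If \code{NULL}, fresh shared fields
#'   are drawn per call.
#' @param mixing_weight Association/unique mixing weight in [0, 1].
#' @param n_freq,n_time Envelope resolution (frequency bins x time knots).
#' @param contrast Log-amplitude scale of the envelope.
#' @param freqs Frequencies (Hz) the envelope rows belong to, used to fix
#'   the per-band envelope energy (see Details); \code{NULL} skips the
#'   normalization.
#' @param norm_bands List of c(lo, hi) bands over which the envelope energy
#'   is fixed; the generator aligns these with the power-analysis bands.
#' @return A positive \code{n_freq x n_time} envelope matrix with the
#'   generating field in attribute \code{"field"}.
#' @export
make_fingerprint <- function(association, assoc_fields = NULL,
                             mixing_weight = 0.3, n_freq = 43, n_time = 26,
                             contrast = 0.7,
                             freqs = frequency_grid()$freq,
                             norm_bands = ers_bands) {
  if (is.null(assoc_fields)) {
    assoc_fields <- stats::setNames(
      list(.smooth_field(n_freq, n_time)), association)
  }
  if (!association %in% names(assoc_fields)) stop("unknown association: ",
                                                  association)
  G <- mixing_weight * assoc_fields[[association]] +
    (1 - mixing_weight) * .smooth_field(n_freq, n_time)
  E <- exp(contrast * G)
  # fix the envelope energy inside each normalization band at every time
  # slice: a trial's band-mean power in any time window must carry no
  # incidental envelope variability (spectral or temporal), so that the
  # power/reinstatement linkage is controlled by the coupling knob alone.
  # Trial identity lives in the within-band spectral profile at each time.
  if (!is.null(freqs)) {
    for (b in norm_bands) {
      rows <- which(freqs >= b[1] & freqs <= b[2])
      if (length(rows) && ncol(E) > 0)
        E[rows, ] <- E[rows, , drop = FALSE] %*%
          diag(1 / sqrt(colMeans(E[rows, , drop = FALSE]^2)), ncol(E))
    }
  }
  structure(E, field = G)
}

# partition of the frequency grid into normalization bands: the two
# measurement bands exactly as configured, plus the contiguous runs of the
# remaining frequencies (alignment matters: a band-mean power measure must
# map onto whole normalization bands, or envelope variability leaks into it)
.norm_bands <- function(freqs, band_a, band_b) {
  ina <- freqs >= band_a[1] & freqs <= band_a[2]
  inb <- freqs >= band_b[1] & freqs <= band_b[2]
  rest <- which(!ina & !inb)
  out <- list()
  if (any(ina)) out[[length(out) + 1L]] <- band_a
  if (any(inb)) out[[length(out) + 1L]] <- band_b
  if (length(rest)) {
    runs <- split(rest, cumsum(c(1L, diff(rest) != 1L)))
    for (r in runs) out[[length(out) + 1L]] <- range(freqs[r])
  }
  out
}

# waveform realising a fingerprint envelope: sum over grid frequencies of
# amplitude-modulated cosines with random phases, Tukey-tapered inside
# `window` (s); `scale` carries per-frequency amplitudes (typically the
# local background spectrum, so the fingerprint produces comparable
# *proportional* power changes at every frequency instead of being
# dominated by the bands where 1/f background is weak); returns the
# full-length vector (zero outside the window)
.fingerprint_signal <- function(fp, freqs, window, times, fs,
                                scale = rep(1, length(freqs)),
                                ramp_frac = 0.15) {
  i0 <- which.min(abs(times - window[1]))
  i1 <- which.min(abs(times - window[2]))
  tw <- times[i0:i1]
  nw <- length(tw)
  E <- scale * (fp %*% t(.interp_basis(nw, ncol(fp)))) # n_freq x nw envelope
  nr <- max(2L, round(ramp_frac * nw))
  taper <- rep(1, nw)
  taper[seq_len(nr)] <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = nr))
  taper[nw + 1 - seq_len(nr)] <- taper[seq_len(nr)]
  ph <- stats::runif(length(freqs), 0, 2 * pi)
  C <- cos(outer(2 * pi * freqs, tw) + ph)        # n_freq x nw carriers
  s <- rep(0, length(times))
  s[i0:i1] <- colSums(E * C) * taper
  s
}

#' Inject a high-amplitude transient artifact into a trace
#'
#' Adds a short damped alternating-sign spike whose amplitude and
#' point-to-point gradient both far exceed the clean ensemble, so that the
#' joint amplitude-and-gradient rejection rule of
#' \code{\link{reject_artifacts}} flags the trial.
#'
#' @param trace Numeric voltage trace.
#' @param position Sample index at which the transient starts.
#' @param scale Amplitude in units of the trace standard deviation;
#'   \code{scale = 0} leaves the trace unchanged.
#' @param duration Transient length in samples.
#' @return The modified trace.
#' @export
inject_artifact <- function(trace, position, scale, duration = 30L) {
  if (position < 1 || position > length(trace)) stop("position inside epoch")
  if (scale == 0) return(trace)
  k <- seq_len(min(duration, length(trace) - position + 1L)) - 1L
  spike <- scale * stats::sd(trace) * (-1)^k * exp(-k / 10)
  trace[position + k] <- trace[position + k] + spike
  trace
}

# shifted truncated log-normal response latencies
.draw_rt <- function(n, mean_s, sd_s, shift, rt_max) {
  mu <- mean_s - shift
  sdlog <- sqrt(log(1 + sd_s^2 / mu^2))
  meanlog <- log(mu) - sdlog^2 / 2
  rt <- shift + stats::rlnorm(n, meanlog, sdlog)
  while (any(rt > rt_max))
    rt[rt > rt_max] <- shift + stats::rlnorm(sum(rt > rt_max), meanlog, sdlog)
  rt
}

#' Generate a synthetic multi-participant encoding/retrieval dataset
#'
#' Simulates single-channel hippocampal voltage epochs for every participant
#' and trial of the configured study, together with the events table and the
#' ground truth needed for recovery testing. Each old trial carries a
#' trial-unique time-frequency fingerprint in the encoding window; AR trials
#' (and only AR trials) additionally receive an amplitude-modulated copy of
#' their own fingerprint in the retrieval window. Condition-level gamma and
#' alpha band effects and occasional high-amplitude artifacts are injected
#' as configured. Output is bit-for-bit reproducible for a fixed seed.
#'
#' @param config An \code{\link{study_config}} object.
#' @return A list with elements \code{encoding} and \code{retrieval}
#'   (\code{\link{epoch_set}} objects pooled over participants),
#'   \code{events} (both phases stacked) and \code{truth} (a
#'   \code{ground_truth} list: per-trial fingerprints, planted windows,
#'   effect descriptors, per-trial modulators and artifact flags).
#' @export
generate_dataset <- function(config) {
  validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  ew <- config$epoch_window
  nsamp <- as.integer(round((ew[2] - ew[1]) * fs)) + 1L
  times <- ew[1] + (seq_len(nsamp) - 1L) / fs
  grid <- frequency_grid()
  fspan <- config$fingerprint$freq_span
  fp_freqs <- grid$freq[grid$freq >= fspan[1] & grid$freq <= fspan[2]]
  nfft <- .next_pow2(nsamp)
  fbins <- (seq_len(nfft) - 1) * fs / nfft
  fbins <- pmin(fbins, fs - fbins)
  amp_spec <- .bg_amp_spectrum(fbins, config$noise_exponent,
                               config$osc_mixture)
  # analytic share of background variance inside a band (for burst scaling)
  band_sd_frac <- function(band) {
    sqrt(sum(amp_spec[fbins >= band[1] & fbins <= band[2]]^2) /
           sum(amp_spec^2))
  }
  sd_g <- band_sd_frac(config$gamma_effect$band)
  sd_a <- band_sd_frac(config$alpha_effect$band)
  # per-frequency fingerprint amplitudes track the background power inside
  # each spectral estimator's equivalent bandwidth (5-cycle Hanning below
  # 30 Hz, +/-10 Hz multitaper above), so the fingerprint produces
  # comparable *proportional* power changes at every analysed frequency --
  # no single band dominates reinstatement. The overall scale divides by
  # the expected RMS of the raw waveform (band-normalized envelopes have
  # unit mean square; each cosine contributes half its squared envelope),
  # making `amplitude` the injected RMS in background-SD units.
  ctr <- config$fingerprint$contrast
  fp_shape <- vapply(fp_freqs, function(f) {
    enbw <- if (f < 30) 0.3 * f else 20     # equivalent noise bandwidths
    sel <- fbins >= f - enbw / 2 & fbins <= f + enbw / 2
    sqrt(sum(amp_spec[sel]^2))
  }, numeric(1))
  fp_scale_vec <- config$base_sd * fp_shape / sqrt(sum(fp_shape^2) / 2)
  win_idx <- function(w) c(which.min(abs(times - w[1])),
                           which.min(abs(times - w[2])))

  n_old <- sum(config$n_trials[c("AR", "IR", "M")])
  n_cr <- config$n_trials[["CR"]]
  enc_list <- list(); ret_list <- list(); ev_list <- list()
  truth <- list(fingerprints = list(),
                enc_window = config$fingerprint$enc_window,
                ret_window = config$fingerprint$ret_window,
                gamma = config$gamma_effect, alpha = config$alpha_effect,
                coupling = config$coupling, modulator = list(),
                artifacts = NULL, mixing_weight =
                  config$fingerprint$mixing_weight)

  for (p in seq_len(config$n_participants)) {
    cond <- rep(c("AR", "IR", "M"), config$n_trials[c("AR", "IR", "M")])
    assoc <- sample(rep(config$associations, length.out = n_old))
    block <- ifelse(assoc %in% config$associations[1:2], "colour", "scene")
    # background traces
    enc <- t(.spectral_noise(nsamp, n_old, amp_spec)) * config$base_sd
    ret <- t(.spectral_noise(nsamp, n_old + n_cr, amp_spec)) * config$base_sd
    # association-shared envelope fields, then per-trial fingerprints
    af <- lapply(config$associations, function(a)
      .smooth_field(length(fp_freqs), config$fingerprint$n_time))
    names(af) <- config$associations
    fps <- vector("list", n_old)
    z <- stats::rnorm(n_old)                   # per-trial coupling latent
    # retrieval-strength modulator: boosts the reinstated fingerprint and
    # gamma power, suppresses alpha power (anti-phase factor below)
    m <- pmax(0.2, 1 + config$coupling * z)
    anti <- pmax(0, 1 - 0.5 * config$coupling * z)
    nb <- .norm_bands(fp_freqs, config$alpha_effect$band,
                      config$gamma_effect$band)
    in_alpha <- fp_freqs >= config$alpha_effect$band[1] &
      fp_freqs <= config$alpha_effect$band[2]
    for (i in seq_len(n_old)) {
      fps[[i]] <- make_fingerprint(assoc[i], af,
                                   config$fingerprint$mixing_weight,
                                   length(fp_freqs),
                                   config$fingerprint$n_time,
                                   contrast = ctr, freqs = fp_freqs,
                                   norm_bands = nb)
      a_fp <- config$fingerprint$amplitude
      if (a_fp > 0) {
        enc[i, ] <- enc[i, ] +
          .fingerprint_signal(fps[[i]], fp_freqs,
                              config$fingerprint$enc_window, times, fs,
                              scale = a_fp * fp_scale_vec)
        if (cond[i] == "AR") {
          # alpha rows follow the anti-phase factor: strong retrieval means
          # more reinstated signal everywhere except the alpha band
          s_ret <- a_fp * fp_scale_vec * ifelse(in_alpha, anti[i], m[i])
          ret[i, ] <- ret[i, ] +
            .fingerprint_signal(fps[[i]], fp_freqs,
                                config$fingerprint$ret_window, times, fs,
                                scale = s_ret)
        }
      }
    }
    # condition-level band effects at retrieval
    ge <- config$gamma_effect; ae <- config$alpha_effect
    if (ge$amplitude > 0) {
      idx <- which(cond == ge$condition)
      if (length(idx)) {
        B <- .band_bursts(nsamp, length(idx), fs, ge$band,
                          win_idx(ge$window))
        amp <- ge$amplitude * (if (ge$condition == "AR") m[idx] else 1)
        ret[idx, ] <- ret[idx, ] +
          t(B) * (amp * sd_g * config$base_sd)
      }
    }
    if (ae$amplitude > 0) {
      idx <- which(cond == ae$condition)
      if (length(idx)) {
        B <- .band_bursts(nsamp, length(idx), fs, ae$band,
                          win_idx(ae$window))
        ret[idx, ] <- ret[idx, ] +
          t(B) * (ae$amplitude * sd_a * config$base_sd)
      }
    }
    if ((ae$ar_amplitude %||% 0) > 0) {
      idx <- which(cond == "AR")
      amp <- ae$ar_amplitude * anti[idx]
      B <- .band_bursts(nsamp, length(idx), fs, ae$band,
                        win_idx(ae$window))
      ret[idx, ] <- ret[idx, ] + t(B) * (amp * sd_a * config$base_sd)
    }
    # response latencies
    rt_of <- function(cs) vapply(cs, function(cc) {
      pars <- config$rt[[cc]]
      .draw_rt(1, pars[1], pars[2], config$rt_shift, config$rt_max)
    }, numeric(1))
    ret_cond <- c(cond, rep("CR", n_cr))
    rts <- rt_of(ret_cond)
    # artifacts
    art_enc <- stats::runif(n_old) < config$artifact_rate
    art_ret <- stats::runif(n_old + n_cr) < config$artifact_rate
    pos_rng <- range(which(times > ew[1] + 0.2 & times < ew[2] - 0.2))
    for (i in which(art_enc))
      enc[i, ] <- inject_artifact(enc[i, ],
                                  sample(pos_rng[1]:pos_rng[2], 1),
                                  config$artifact_scale)
    for (i in which(art_ret))
      ret[i, ] <- inject_artifact(ret[i, ],
                                  sample(pos_rng[1]:pos_rng[2], 1),
                                  config$artifact_scale)

    ev_enc <- data.frame(participant = p, trial = seq_len(n_old),
                         phase = "encoding", condition = cond,
                         association = assoc, block_type = block,
                         rt_s = NA_real_, old_new = "old",
                         is_artifact = art_enc)
    ev_ret <- data.frame(participant = p,
                         trial = seq_len(n_old + n_cr),
                         phase = "retrieval", condition = ret_cond,
                         association = c(assoc, rep(NA_character_, n_cr)),
                         block_type = c(block,
                                        sample(c("colour", "scene"), n_cr,
                                               replace = TRUE)),
                         rt_s = rts,
                         old_new = c(rep("old", n_old), rep("new", n_cr)),
                         is_artifact = art_ret)
    enc_list[[p]] <- enc; ret_list[[p]] <- ret
    ev_list[[p]] <- rbind(ev_enc, ev_ret)
    truth$fingerprints[[p]] <- fps
    truth$modulator[[p]] <- m
  }
  events <- do.call(rbind, ev_list)
  truth$artifacts <- events[events$is_artifact,
                            c("participant", "trial", "phase")]
  enc_ev <- events[events$phase == "encoding", ]
  ret_ev <- events[events$phase == "retrieval", ]
  list(encoding = epoch_set(do.call(rbind, enc_list), times, fs,
                            "stimulus", enc_ev),
       retrieval = epoch_set(do.call(rbind, ret_list), times, fs,
                             "stimulus", ret_ev),
       events = validate_events(events, config$rt_max),
       truth = structure(truth, class = "ground_truth"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
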