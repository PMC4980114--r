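#' @name pattern-variants
#' @title Representational pattern variants
#' @description
#' A representational pattern is the relative-power content of a short
#' time-frequency window centred on a time point: \code{tf_400ms} (43 x 41
#' values, the reference), \code{freqs_only} (43 x 1, the frequency profile
#' at the centre bin), \code{tf_500ms} (43 x 51) and \code{avg_500ms} (43
#' values, time-averaged over the 500-ms window).
NULL

.variant_half_bins <- function(variant) {
  switch(variant,
         tf_400ms = 20L, freqs_only = 0L, tf_500ms = 25L, avg_500ms = 25L,
         stop("unknown pattern variant: ", variant))
}

.variant_averaged <- function(variant) identical(variant, "avg_500ms")

#' Canonical frequency bands of the analysis grid
#'
#' Band boundaries (Hz, inclusive) used by the band exclusion/inclusion
#' analysis: delta 2-3, theta 4-7, alpha 8-12, beta 13-29, gamma1 30-50,
#' gamma2 55-100.
#' @export
ers_bands <- list(delta = c(2, 3), theta = c(4, 7), alpha = c(8, 12),
                  beta = c(13, 29), gamma1 = c(30, 50), gamma2 = c(55, 100))

# indices of pattern-centre time bins whose full pattern window is valid for
# every frequency; for response-locked TFRs `trial` refines with that
# trial's validity
.pattern_centre_idx <- function(tfr, variant, trial = NULL) {
  h <- .variant_half_bins(variant)
  nt <- length(tfr$times)
  allv <- apply(tfr$valid, 2, all)
  if (!is.null(trial) && !is.null(tfr$trial_valid))
    allv <- allv & tfr$trial_valid[trial, ]
  ok <- logical(nt)
  for (c in seq_len(nt)) {
    if (c - h < 1L || c + h > nt) next
    ok[c] <- all(allv[(c - h):(c + h)])
  }
  which(ok)
}

#' Pattern-centre times available for a TFR and variant
#' @param tfr An \code{ers_tfr} (normalized).
#' @param variant Pattern variant, see \link{pattern-variants}.
#' @return Numeric vector of centre times (s).
#' @export
pattern_centres <- function(tfr, variant = "tf_400ms") {
  tfr$times[.pattern_centre_idx(tfr, variant)]
}

#' Extract a representational pattern
#'
#' @param tfr A normalized \code{ers_tfr}.
#' @param trial Trial index.
#' @param centre Centre time (s); must be a valid pattern centre.
#' @param variant Pattern variant, see \link{pattern-variants}.
#' @param freq_rows Optional integer subset of frequency rows (band
#'   restriction).
#' @return A frequency x window-time matrix of relative power (one column
#'   for \code{freqs_only}/\code{avg_500ms}).
#' @export
extract_pattern <- function(tfr, trial, centre, variant = "tf_400ms",
                            freq_rows = NULL) {
  h <- .variant_half_bins(variant)
  ci <- which(abs(tfr$times - centre) < 1e-9)
  if (!length(ci)) stop("centre not on the time grid")
  if (!(ci %in% .pattern_centre_idx(tfr, variant, trial)))
    stop("pattern window out of the valid range")
  if (is.null(freq_rows)) freq_rows <- seq_along(tfr$freqs)
  P <- tfr$power[trial, freq_rows, (ci - h):(ci + h), drop = TRUE]
  P <- matrix(P, nrow = length(freq_rows))
  if (.variant_averaged(variant)) P <- matrix(rowMeans(P), ncol = 1)
  structure(P, centre = centre, variant = variant,
            freqs = tfr$freqs[freq_rows])
}

# centres x p matrix of row-standardized (centred, unit-norm) average ranks
# of the vectorized patterns of one trial; NA rows mark centres that are
# invalid for this trial or have constant patterns. Ranking happens in
# compiled code (.std_rank_cols).
.rank_pattern_matrix <- function(tfr, trial, variant, freq_rows = NULL,
                                 centre_idx = NULL) {
  h <- .variant_half_bins(variant)
  if (is.null(centre_idx)) centre_idx <- .pattern_centre_idx(tfr, variant)
  if (is.null(freq_rows)) freq_rows <- seq_along(tfr$freqs)
  avg <- .variant_averaged(variant)
  nf <- length(freq_rows)
  nw <- 2L * h + 1L
  nc <- length(centre_idx)
  P_all <- tfr$power[trial, freq_rows, , drop = TRUE]
  if (nf == 1L) P_all <- matrix(P_all, nrow = 1L)
  if (!is.null(tfr$trial_valid))
    P_all[, !tfr$trial_valid[trial, ]] <- NA_real_
  if (!avg)
    return(t(.std_rank_windows(P_all, centre_idx - 1L, h)))
  # time-averaged variant: gather, average over the window, rank
  cols <- outer(seq(-h, h), centre_idx, `+`)
  V <- matrix(P_all[, as.vector(cols)], nrow = nf * nw)
  V <- array(V, c(nf, nw, nc))
  V <- matrix(colMeans(aperm(V, c(2, 1, 3))), nrow = nf)
  t(.std_rank_cols(V))
}

# rho map from two standardized rank matrices; NA rows handled by masking
# so the BLAS fast path is kept
.map_product <- function(Ze, Zr) {
  oke <- !is.na(Ze[, 1])
  okr <- !is.na(Zr[, 1])
  map <- matrix(NA_real_, nrow(Ze), nrow(Zr))
  if (any(oke) && any(okr))
    map[oke, okr] <- tcrossprod(Ze[oke, , drop = FALSE],
                                Zr[okr, , drop = FALSE])
  map
}

.new_map <- function(m, enc_times, ret_times, scale = "rho",
                     lock = "stimulus", provenance = "own") {
  structure(m, enc_times = enc_times, ret_times = ret_times, scale = scale,
            lock = lock, provenance = provenance, class = "ers_map")
}

#' @export
print.ers_map <- function(x, ...) {
  cat("<ers_map> ", nrow(x), " enc x ", ncol(x), " ret bins, scale=",
      attr(x, "scale"), ", lock=", attr(x, "lock"), ", provenance=",
      attr(x, "provenance"), "\n", sep = "")
  invisible(x)
}

#' Trial-wise encoding x retrieval reinstatement map
#'
#' Slides the pattern window in 10-ms steps over all valid centres of the
#' encoding and retrieval TFRs and computes, for every centre pair, the
#' Spearman rank correlation between the vectorized encoding and retrieval
#' patterns.
#'
#' @param enc_tfr,ret_tfr Normalized \code{ers_tfr} objects (identical
#'   normalization).
#' @param enc_trial,ret_trial Trial indices into the two TFRs.
#' @param variant Pattern variant, see \link{pattern-variants}.
#' @param freq_rows Optional frequency-row subset (band restriction).
#' @return An \code{ers_map}: encoding-time x retrieval-time matrix of rho
#'   values with centre times in attributes.
#' @export
reinstatement_map <- function(enc_tfr, ret_tfr, enc_trial, ret_trial,
                              variant = "tf_400ms", freq_rows = NULL) {
  if (enc_tfr$normalization != ret_tfr$normalization)
    stop("encoding and retrieval TFRs must share a normalization")
  eci <- .pattern_centre_idx(enc_tfr, variant)
  rci <- .pattern_centre_idx(ret_tfr, variant)
  Ze <- .rank_pattern_matrix(enc_tfr, enc_trial, variant, freq_rows, eci)
  Zr <- .rank_pattern_matrix(ret_tfr, ret_trial, variant, freq_rows, rci)
  .new_map(.map_product(Ze, Zr), enc_tfr$times[eci], ret_tfr$times[rci],
           lock = ret_tfr$lock)
}

#' Average reinstatement maps over trials
#'
#' Elementwise mean over a list of congruent maps (rho scale). Bins missing
#' in more than \code{1 - min_frac} of the trials are NA.
#'
#' @param maps List of \code{ers_map} objects (or matrices).
#' @param min_frac Minimum fraction of contributing trials per bin.
#' @return An \code{ers_map}.
#' @export
condition_average <- function(maps, min_frac = 0.5) {
  if (!length(maps)) stop("no maps to average")
  a <- maps[[1]]
  s <- matrix(0, nrow(a), ncol(a)); n <- s
  for (m in maps) {
    ok <- !is.na(m)
    s[ok] <- s[ok] + m[ok]
    n <- n + ok
  }
  out <- ifelse(n >= max(1, min_frac * length(maps)), s / pmax(n, 1),
                NA_real_)
  .new_map(out, attr(a, "enc_times"), attr(a, "ret_times"),
           attr(a, "scale") %||% "rho", attr(a, "lock") %||% "stimulus",
           attr(a, "provenance") %||% "own")
}

#' Fisher z transform
#'
#' \code{atanh(rho)}; values with |rho| >= 1 are clipped to
#' +/-(1 - 1e-6) with a warning.
#' @param rho Correlation value(s), matrix or vector; NA passed through.
#' @return Transformed values (same shape).
#' @export
fisher_z <- function(rho) {
  bad <- !is.na(rho) & abs(rho) >= 1
  if (any(bad)) {
    warning(sum(bad), " correlation value(s) with |rho| >= 1 clipped")
    rho[bad] <- sign(rho[bad]) * (1 - 1e-6)
  }
  atanh(rho)
}

#' Per-frequency correlation weights of a pattern pair
#'
#' Decomposes the Spearman correlation between two patterns into additive
#' per-frequency contributions: both vectorized patterns are rank-transformed
#' and standardized such that the mean of elementwise products equals the
#' correlation coefficient; products are reshaped to frequency x time and
#' summed over time. The weights sum to the Spearman rho of the pair.
#'
#' @param enc_pattern,ret_pattern Frequency x window-time matrices (from
#'   \code{\link{extract_pattern}}), non-constant.
#' @return Numeric vector of per-frequency weights.
#' @export
correlation_weights <- function(enc_pattern, ret_pattern) {
  stopifnot(all(dim(enc_pattern) == dim(ret_pattern)))
  nf <- nrow(enc_pattern)
  std_rank <- function(x) {
    r <- rank(as.vector(x))
    if (stats::sd(r) == 0) stop("constant pattern: correlation undefined")
    (r - mean(r)) / stats::sd(r)
  }
  zx <- std_rank(enc_pattern)
  zy <- std_rank(ret_pattern)
  w <- matrix(zx * zy / (length(zx) - 1), nrow = nf)
  rowSums(w)
}

#' Band-restricted reinstatement map
#'
#' Reinstatement map computed after excluding, or only including, the
#' frequency rows of one canonical band (see \code{\link{ers_bands}}).
#'
#' @inheritParams reinstatement_map
#' @param band Band name (one of \code{names(ers_bands)}) or c(lo, hi) Hz.
#' @param mode \code{"exclude"} or \code{"only"}.
#' @return An \code{ers_map}.
#' @export
band_restricted_map <- function(enc_tfr, ret_tfr, enc_trial, ret_trial,
                                band, mode = c("exclude", "only"),
                                variant = "tf_400ms") {
  mode <- match.arg(mode)
  if (is.character(band)) {
    if (!band %in% names(ers_bands)) stop("unknown band: ", band)
    band <- ers_bands[[band]]
  }
  inband <- enc_tfr$freqs >= band[1] & enc_tfr$freqs <= band[2]
  rows <- if (mode == "only") which(inband) else which(!inband)
  if (!length(rows)) stop("empty retained frequency set")
  reinstatement_map(enc_tfr, ret_tfr, enc_trial, ret_trial, variant,
                    freq_rows = rows)
}

#' Association-matched surrogate reinstatement map
#'
#' For every AR trial, its retrieval patterns are correlated with the
#' encoding patterns of all \emph{other} AR trials that carry exactly the
#' same target association; these surrogate maps are averaged per trial and
#' then over trials into a single participant surrogate map. Controls for
#' perceptual/category-level similarity while preserving the marginal
#' time-frequency statistics. AR trials whose association has no other AR
#' trial are skipped (counted in attribute \code{"skipped"}).
#'
#' @param enc_tfr,ret_tfr Normalized \code{ers_tfr} objects whose events
#'   tables carry \code{trial}, \code{condition} and \code{association}.
#' @param variant Pattern variant.
#' @param freq_rows Optional frequency-row subset.
#' @return An \code{ers_map} with provenance \code{"surrogate"}.
#' @export
surrogate_maps <- function(enc_tfr, ret_tfr, variant = "tf_400ms",
                           freq_rows = NULL) {
  pr <- participant_reinstatement(enc_tfr, ret_tfr, variant = variant,
                                  freq_rows = freq_rows,
                                  conditions = "AR")
  pr$AR_surrogate
}

#' Per-participant reinstatement maps (own, condition and surrogate)
#'
#' Batch engine behind the per-participant stage of the pipeline: computes
#' the trial-wise own reinstatement maps for each requested condition, their
#' condition averages, the association-matched AR surrogate map, and
#' (optionally) per-AR-trial mean reinstatement inside an
#' encoding x retrieval window of interest.
#'
#' @param enc_tfr,ret_tfr Normalized \code{ers_tfr} objects with linked
#'   events (one participant). Trials are matched across phases by the
#'   \code{trial} column; artifact trials are expected to be already
#'   excluded.
#' @param variant Pattern variant.
#' @param freq_rows Optional frequency-row subset.
#' @param conditions Conditions to average (subset of AR/IR/M).
#' @param window Optional \code{list(enc = c(lo, hi), ret = c(lo, hi))}
#'   (s) for per-trial windowed reinstatement values of AR trials.
#' @return A list: condition maps (\code{AR}, \code{IR}, ...),
#'   \code{AR_surrogate}, \code{ar_values} (per-trial windowed means),
#'   \code{ar_trials} (their trial ids), and \code{n} per condition.
#' @export
participant_reinstatement <- function(enc_tfr, ret_tfr,
                                      variant = "tf_400ms",
                                      freq_rows = NULL,
                                      conditions = c("AR", "IR"),
                                      window = NULL) {
  enc_ev <- enc_tfr$events
  ret_ev <- ret_tfr$events
  if (is.null(enc_ev) || is.null(ret_ev)) stop("TFRs must carry events")
  eci <- .pattern_centre_idx(enc_tfr, variant)
  rci <- .pattern_centre_idx(ret_tfr, variant)
  enc_times <- enc_tfr$times[eci]
  ret_times <- ret_tfr$times[rci]
  wmask <- NULL
  if (!is.null(window))
    wmask <- outer(enc_times >= window$enc[1] - 1e-9 &
                     enc_times <= window$enc[2] + 1e-9,
                   ret_times >= window$ret[1] - 1e-9 &
                     ret_times <= window$ret[2] + 1e-9, `&`)

  out <- list(n = integer(0))
  # encoding rank matrices for all trials that have a clean retrieval pair
  usable <- intersect(enc_ev$trial, ret_ev$trial[ret_ev$condition %in%
                                                   conditions])
  Ze <- list()
  for (tr in usable) {
    i <- which(enc_ev$trial == tr)
    Ze[[as.character(tr)]] <-
      .rank_pattern_matrix(enc_tfr, i, variant, freq_rows, eci)
  }
  ar_values <- numeric(0); ar_trials <- integer(0)
  ar_Zr <- list()
  for (cond in conditions) {
    trs <- intersect(ret_ev$trial[ret_ev$condition == cond], usable)
    if (!length(trs)) { out[[cond]] <- NULL; out$n[cond] <- 0L; next }
    s <- NULL; cnt <- NULL
    for (tr in trs) {
      j <- which(ret_ev$trial == tr)
      Zr <- .rank_pattern_matrix(ret_tfr, j, variant, freq_rows, rci)
      m <- .map_product(Ze[[as.character(tr)]], Zr)
      if (cond == "AR") {
        ar_Zr[[as.character(tr)]] <- Zr
        ar_trials <- c(ar_trials, tr)
        if (!is.null(wmask))
          ar_values <- c(ar_values, mean(m[wmask], na.rm = TRUE))
      }
      ok <- !is.na(m)
      if (is.null(s)) { s <- matrix(0, nrow(m), ncol(m)); cnt <- s }
      s[ok] <- s[ok] + m[ok]
      cnt <- cnt + ok
    }
    avg <- ifelse(cnt >= max(1, 0.5 * length(trs)), s / pmax(cnt, 1),
                  NA_real_)
    out[[cond]] <- .new_map(avg, enc_times, ret_times, lock = ret_tfr$lock)
    out$n[cond] <- length(trs)
  }
  # association-matched surrogates over AR trials
  skipped <- 0L
  s <- NULL; cnt <- NULL
  if (length(ar_trials)) {
    assoc <- ret_ev$association[match(ar_trials, ret_ev$trial)]
    Zsum <- list()
    for (a in unique(assoc)) {
      ids <- as.character(ar_trials[assoc == a])
      if (length(ids) < 2) next
      acc <- 0
      for (id in ids) {
        Zi <- Ze[[id]]
        Zi[is.na(Zi)] <- 0
        acc <- acc + Zi
      }
      Zsum[[a]] <- acc
    }
    for (k in seq_along(ar_trials)) {
      a <- assoc[k]; id <- as.character(ar_trials[k])
      ids <- ar_trials[assoc == a]
      if (length(ids) < 2 || is.null(Zsum[[a]])) { skipped <- skipped + 1L
        next }
      Zi <- Ze[[id]]
      Zi[is.na(Zi)] <- 0
      Zother <- (Zsum[[a]] - Zi) / (length(ids) - 1L)
      # rows where every partner was NA end up all-zero; treat as NA
      zero <- rowSums(abs(Zother)) == 0
      Zother[zero, ] <- NA_real_
      m <- .map_product(Zother, ar_Zr[[id]])
      ok <- !is.na(m)
      if (is.null(s)) { s <- matrix(0, nrow(m), ncol(m)); cnt <- s }
      s[ok] <- s[ok] + m[ok]
      cnt <- cnt + ok
    }
  }
  if (!is.null(s)) {
    n_used <- length(ar_trials) - skipped
    avg <- ifelse(cnt >= max(1, 0.5 * n_used), s / pmax(cnt, 1), NA_real_)
    out$AR_surrogate <- .new_map(avg, enc_times, ret_times,
                                 lock = ret_tfr$lock,
                                 provenance = "surrogate")
    attr(out$AR_surrogate, "skipped") <- skipped
  }
  out$ar_values <- ar_values
  out$ar_trials <- ar_trials
  out
}

#' Mean of a reinstatement map inside an encoding x retrieval window
#' @param map An \code{ers_map}.
#' @param enc_window,ret_window c(lo, hi) windows in seconds.
#' @return Scalar mean (NA bins excluded).
#' @export
map_window_mean <- function(map, enc_window, ret_window) {
  et <- attr(map, "enc_times"); rt <- attr(map, "ret_times")
  sel <- outer(et >= enc_window[1] - 1e-9 & et <= enc_window[2] + 1e-9,
               rt >= ret_window[1] - 1e-9 & rt <= ret_window[2] + 1e-9, `&`)
  if (!any(sel)) stop("window outside the map grid")
  mean(map[sel], na.rm = TRUE)
}
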