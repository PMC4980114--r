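#' Analysis configuration for the reinstatement pipeline
#'
#' Collects the analytic choices of the end-to-end analysis: pattern
#' variant, band/window definitions of the gamma and alpha effects, the
#' encoding x retrieval window of interest, cluster-test settings and which
#' optional stages to run.
#'
#' @param variant Pattern variant, see \link{pattern-variants}.
#' @param gamma_band,gamma_window Gamma effect definition (Hz, s).
#' @param alpha_band,alpha_window Alpha effect definition (Hz, s).
#' @param enc_window,ret_window Encoding x retrieval reinstatement window of
#'   interest (s, stimulus-locked).
#' @param resp_ret_window Retrieval window of interest relative to the
#'   response (s), used by the response-locked stage.
#' @param baseline Baseline window (s) for relative power.
#' @param tfr_range Time range (s) over which the TFR is computed.
#' @param tf_test_range Time range (s) of the group time-frequency contrast.
#' @param alpha_cf Cluster-forming alpha (two-tailed for t).
#' @param n_perm Number of permutations for cluster tests.
#' @param response_locked Run the response-locked stage.
#' @param crossband Run the cross-band correlation stage.
#' @param seed Seed for the permutation draws.
#' @return A list of class \code{ers_analysis}.
#' @export
analysis_config <- function(variant = "tf_400ms",
                            gamma_band = c(50, 90),
                            gamma_window = c(0.5, 1.3),
                            alpha_band = c(8, 12),
                            alpha_window = c(1, 2),
                            enc_window = c(0.5, 1),
                            ret_window = c(1, 1.5),
                            resp_ret_window = c(-0.8, -0.2),
                            baseline = c(-0.5, 0),
                            tfr_range = c(-0.5, 2.5),
                            tf_test_range = c(0, 2.5),
                            alpha_cf = 0.05, n_perm = 1000,
                            response_locked = TRUE, crossband = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "ers_analysis")
}

# window -> logical mask helpers on map / TF grids
.win_mask_map <- function(map, enc_window, ret_window) {
  et <- attr(map, "enc_times"); rt <- attr(map, "ret_times")
  outer(et >= enc_window[1] - 1e-9 & et <= enc_window[2] + 1e-9,
        rt >= ret_window[1] - 1e-9 & rt <= ret_window[2] + 1e-9, `&`)
}

.win_mask_tf <- function(freqs, times, band, twin) {
  outer(freqs >= band[1] & freqs <= band[2],
        times >= twin[1] - 1e-9 & times <= twin[2] + 1e-9, `&`)
}

# does any significant cluster of the given sign overlap the window mask?
.cluster_overlap <- function(res, wmask, sign = 1, alpha = 0.05) {
  any(significant_mask(res, alpha, sign) & wmask)
}

#' Run the full simulated reinstatement analysis
#'
#' Executes all stages on a synthetic dataset: simulation (or a supplied
#' dataset), artifact rejection, time-frequency decomposition with baseline
#' normalization, trial-wise reinstatement maps with association-matched
#' surrogates, group cluster statistics (AR vs IR, AR vs surrogate and
#' their min-t conjunction; AR vs IR time-frequency contrast), band time
#' courses, median-split linkage of gamma/alpha power with reinstatement,
#' optional cross-band correlation and response-locked stages, and a
#' ground-truth recovery summary.
#'
#' @param config A \code{\link{study_config}}.
#' @param analysis An \code{\link{analysis_config}}.
#' @param dataset Optional pre-generated dataset (as returned by
#'   \code{\link{generate_dataset}}); when supplied, \code{config} is only
#'   used for its planted-effect metadata.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class \code{ers_report}; see the package vignette for
#'   the component layout.
#' @export
run_pipeline <- function(config = study_config(),
                         analysis = analysis_config(),
                         dataset = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  tf_times <- NULL
  if (is.null(dataset)) {
    say("simulate: generating dataset")
    dataset <- generate_dataset(config)
  }
  an <- analysis
  parts <- sort(unique(dataset$events$participant))
  per <- list()
  rej_rows <- list()
  say("analyze: per-participant decomposition and maps")
  for (p in parts) {
    enc <- dataset$encoding[dataset$encoding$events$participant == p]
    ret <- dataset$retrieval[dataset$retrieval$events$participant == p]
    ra_e <- reject_artifacts(enc)
    ra_r <- reject_artifacts(ret)
    rej_rows[[length(rej_rows) + 1L]] <- data.frame(
      participant = p,
      n_enc = nrow(enc$data), rej_enc = sum(ra_e$rejected),
      n_ret = nrow(ret$data), rej_ret = sum(ra_r$rejected))
    tfr_e <- baseline_normalize(
      tfr_transform(ra_e$clean, t_range = an$tfr_range),
      window = an$baseline)
    tfr_r <- baseline_normalize(
      tfr_transform(ra_r$clean, t_range = an$tfr_range),
      window = an$baseline)
    if (is.null(tf_times)) tf_times <- tfr_r$times
    pr <- participant_reinstatement(
      tfr_e, tfr_r, variant = an$variant,
      window = list(enc = an$enc_window, ret = an$ret_window))
    ev_r <- tfr_r$events
    ar_idx <- match(pr$ar_trials, ev_r$trial)
    ir_idx <- which(ev_r$condition == "IR")
    gpow <- cluster_mean_power(tfr_r, an$gamma_band, an$gamma_window,
                               trials = ar_idx)
    apow <- cluster_mean_power(tfr_r, an$alpha_band, an$alpha_window,
                               trials = ar_idx)
    cond_tf <- function(cond) {
      idx <- which(ev_r$condition == cond)
      m <- apply(tfr_r$power[idx, , , drop = FALSE], c(2, 3), mean)
      m[!tfr_r$valid] <- NA_real_
      m
    }
    entry <- list(
      maps = list(AR = pr$AR, IR = pr$IR, surrogate = pr$AR_surrogate),
      ar_values = pr$ar_values, ar_trials = pr$ar_trials,
      gamma_power = gpow, alpha_power = apow,
      tf = list(AR = cond_tf("AR"), IR = cond_tf("IR")),
      gamma_tc = list(AR = band_timecourse(tfr_r, an$gamma_band,
                                           which(ev_r$condition == "AR"))$mean,
                      IR = band_timecourse(tfr_r, an$gamma_band, ir_idx)$mean),
      alpha_tc = list(AR = band_timecourse(tfr_r, an$alpha_band,
                                           which(ev_r$condition == "AR"))$mean,
                      IR = band_timecourse(tfr_r, an$alpha_band, ir_idx)$mean))
    if (an$crossband) {
      cb <- function(cond) {
        idx <- which(ev_r$condition == cond)
        if (length(idx) < 10) return(NULL)
        crossband_correlation(tfr_r, an$gamma_band, an$alpha_band,
                              time_range = c(min(an$gamma_window[1],
                                                 an$alpha_window[1]),
                                             max(an$gamma_window[2],
                                                 an$alpha_window[2])),
                              trials = idx)$r
      }
      rA <- cb("AR"); rI <- cb("IR")
      entry$crossband <- if (is.null(rI)) rA else if (is.null(rA)) rI else
        (rA + rI) / 2
      # window-mean band powers per condition (for the across-participant
      # correlation), collapsed across AR and IR
      gp <- cluster_mean_power(tfr_r, an$gamma_band, an$gamma_window,
                               trials = which(ev_r$condition %in%
                                                c("AR", "IR")))
      ap <- cluster_mean_power(tfr_r, an$alpha_band, an$alpha_window,
                               trials = which(ev_r$condition %in%
                                                c("AR", "IR")))
      entry$gamma_mean <- mean(gp); entry$alpha_mean <- mean(ap)
    }
    if (an$response_locked) {
      tfr_rl <- response_lock_tfr(tfr_r, window = c(-1, 0.1))
      prl <- participant_reinstatement(
        tfr_e, tfr_rl, variant = an$variant,
        window = list(enc = an$enc_window, ret = an$resp_ret_window))
      ev_rl <- tfr_rl$events
      cond_tf_rl <- function(cond) {
        idx <- which(ev_rl$condition == cond)
        m <- apply(tfr_rl$power[idx, , , drop = FALSE], c(2, 3),
                   function(v) mean(v, na.rm = TRUE))
        m[, colSums(tfr_rl$trial_valid[idx, , drop = FALSE]) <
            0.5 * length(idx)] <- NA_real_
        m
      }
      entry$resp <- list(
        maps = list(AR = prl$AR, IR = prl$IR,
                    surrogate = prl$AR_surrogate),
        tf = list(AR = cond_tf_rl("AR"), IR = cond_tf_rl("IR")),
        times = tfr_rl$times)
    }
    per[[as.character(p)]] <- entry
    say("  participant ", p, " done")
  }
  freqs <- frequency_grid()$freq

  say("stats: group-level cluster tests")
  zmaps <- function(key) lapply(per, function(e) fisher_z(e$maps[[key]]))
  res_ar_ir <- cluster_permutation_paired(zmaps("AR"), zmaps("IR"),
                                          alpha_cf = an$alpha_cf,
                                          n_perm = an$n_perm,
                                          seed = an$seed)
  res_ar_surr <- cluster_permutation_paired(zmaps("AR"), zmaps("surrogate"),
                                            alpha_cf = an$alpha_cf,
                                            n_perm = an$n_perm,
                                            seed = an$seed + 1L)
  conj <- conjunction_min_t(res_ar_ir, res_ar_surr)
  tf_sel <- tf_times >= an$tf_test_range[1] - 1e-9 &
    tf_times <= an$tf_test_range[2] + 1e-9
  tf_of <- function(key) lapply(per, function(e) e$tf[[key]][, tf_sel])
  res_tf <- cluster_permutation_paired(tf_of("AR"), tf_of("IR"),
                                       alpha_cf = an$alpha_cf,
                                       n_perm = an$n_perm,
                                       seed = an$seed + 2L)
  tf_test_times <- tf_times[tf_sel]

  # median-split linkage per participant, then group contrasts
  ms <- lapply(per, function(e) {
    if (length(e$ar_values) < 4 || stats::sd(e$gamma_power) == 0 ||
        stats::sd(e$alpha_power) == 0) return(NULL)
    list(g = median_split_linkage(e$gamma_power, e$ar_values),
         a = median_split_linkage(e$alpha_power, e$ar_values))
  })
  ms <- ms[!vapply(ms, is.null, logical(1))]
  cells <- t(vapply(ms, function(m)
    c(gh = m$g$high, gl = m$g$low, ah = m$a$high, al = m$a$low),
    numeric(4)))
  median_split <- list(cells = cells)
  if (nrow(cells) >= 2) {
    median_split$gamma_t <- stats::t.test(cells[, "gh"], cells[, "gl"],
                                          paired = TRUE)
    median_split$alpha_t <- stats::t.test(cells[, "ah"], cells[, "al"],
                                          paired = TRUE)
    # factors: power level (high, low) x band (gamma, alpha)
    median_split$interaction <- rm_anova_2x2(
      cells[, c("gh", "ah", "gl", "al")])
  }

  # reinstatement values in the window of interest (rho scale)
  roi <- vapply(per, function(e) {
    vapply(e$maps, function(m)
      if (is.null(m)) NA_real_ else
        map_window_mean(m, an$enc_window, an$ret_window), numeric(1))
  }, numeric(3))

  report <- list(
    config = config, analysis = an,
    rejection = do.call(rbind, rej_rows),
    participants = per,
    freqs = freqs, tf_times = tf_times, tf_test_times = tf_test_times,
    tests = list(ar_vs_ir = res_ar_ir, ar_vs_surrogate = res_ar_surr,
                 conjunction = conj, tf_ar_vs_ir = res_tf),
    roi_values = roi,
    median_split = median_split)

  if (an$crossband) {
    say("stats: cross-band correlations")
    cbs <- lapply(per, function(e) e$crossband)
    cbs <- cbs[!vapply(cbs, is.null, logical(1))]
    if (length(cbs) >= 2) {
      d <- min(vapply(cbs, nrow, integer(1)))
      cbs <- lapply(cbs, function(m) m[seq_len(d), seq_len(d)])
      report$crossband <- list(
        group = crossband_group_test(cbs, alpha_cf = an$alpha_cf,
                                     n_perm = an$n_perm,
                                     seed = an$seed + 3L),
        across_participants = across_participant_correlation(
          vapply(per, `[[`, numeric(1), "gamma_mean"),
          vapply(per, `[[`, numeric(1), "alpha_mean")))
    }
  }

  if (an$response_locked) {
    say("stats: response-locked contrasts")
    zr <- function(key) lapply(per, function(e) fisher_z(e$resp$maps[[key]]))
    rl_ar_ir <- cluster_permutation_paired(zr("AR"), zr("IR"),
                                           alpha_cf = an$alpha_cf,
                                           n_perm = an$n_perm,
                                           seed = an$seed + 4L)
    rl_ar_surr <- cluster_permutation_paired(zr("AR"), zr("surrogate"),
                                             alpha_cf = an$alpha_cf,
                                             n_perm = an$n_perm,
                                             seed = an$seed + 5L)
    rl_tf <- cluster_permutation_paired(
      lapply(per, function(e) e$resp$tf$AR),
      lapply(per, function(e) e$resp$tf$IR),
      alpha_cf = an$alpha_cf, n_perm = an$n_perm, seed = an$seed + 6L)
    report$response_locked <- list(
      ar_vs_ir = rl_ar_ir, ar_vs_surrogate = rl_ar_surr,
      conjunction = conjunction_min_t(rl_ar_ir, rl_ar_surr),
      tf_ar_vs_ir = rl_tf,
      times = per[[1]]$resp$times)
  }

  # ground-truth recovery summary (only meaningful for simulated data)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    m1 <- per[[1]]$maps$AR
    wmask <- .win_mask_map(m1, tr$enc_window, tr$ret_window)
    gmask <- .win_mask_tf(freqs, tf_test_times, tr$gamma$band,
                          tr$gamma$window)
    amask <- .win_mask_tf(freqs, tf_test_times, tr$alpha$band,
                          tr$alpha$window)
    report$recovery <- list(
      conjunction_hit = any(conj$mask & wmask),
      gamma_hit = .cluster_overlap(res_tf, gmask, sign = 1),
      alpha_hit = .cluster_overlap(res_tf, amask, sign = -1),
      mean_ar_rho = mean(roi["AR", ]),
      mean_ir_rho = mean(roi["IR", ]),
      mean_surrogate_rho = mean(roi["surrogate", ]))
  }
  report$runtime_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  structure(report, class = "ers_report")
}

#' @export
print.ers_report <- function(x, ...) {
  cat("<ers_report> ", nrow(x$rejection), " participants, runtime ",
      sprintf("%.1f", x$runtime_s), " s\n", sep = "")
  cat("rejected trials: ",
      sum(x$rejection$rej_enc + x$rejection$rej_ret), "/",
      sum(x$rejection$n_enc + x$rejection$n_ret), "\n", sep = "")
  cat("\nAR vs IR reinstatement:\n"); print(x$tests$ar_vs_ir)
  cat("AR vs surrogate reinstatement:\n"); print(x$tests$ar_vs_surrogate)
  cat("conjunction bins: ", sum(x$tests$conjunction$mask), "\n", sep = "")
  cat("TF AR vs IR:\n"); print(x$tests$tf_ar_vs_ir)
  if (!is.null(x$median_split$gamma_t))
    cat(sprintf("median split (gamma): high %.4f vs low %.4f, t(%d) = %.2f\n",
                mean(x$median_split$cells[, "gh"]),
                mean(x$median_split$cells[, "gl"]),
                nrow(x$median_split$cells) - 1,
                unname(x$median_split$gamma_t$statistic)))
  if (!is.null(x$recovery)) {
    cat("recovery: conjunction_hit=", x$recovery$conjunction_hit,
        " gamma_hit=", x$recovery$gamma_hit,
        " alpha_hit=", x$recovery$alpha_hit,
        sprintf(" mean AR rho=%.4f", x$recovery$mean_ar_rho), "\n",
        sep = "")
  }
  invisible(x)
}
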