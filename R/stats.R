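#' Median-split linkage of band power and reinstatement
#'
#' Partitions trials at the median of their power values and returns the
#' mean reinstatement of the high- and low-power halves. With an odd number
#' of trials the median trial is excluded.
#'
#' @param power Per-trial scalar power values (e.g. from
#'   \code{\link{cluster_mean_power}}).
#' @param reinstatement Per-trial reinstatement values (same length), e.g.
#'   windowed means of the trial maps.
#' @return A list: \code{high}, \code{low} (mean reinstatement per half),
#'   \code{n_half}, and the index vectors \code{high_trials},
#'   \code{low_trials}.
#' @export
median_split_linkage <- function(power, reinstatement) {
  stopifnot(length(power) == length(reinstatement))
  n <- length(power)
  if (n < 4) stop("need at least 4 trials")
  if (stats::sd(power) == 0) stop("all power values are equal")
  o <- order(power)
  nh <- n %/% 2L
  low_i <- o[seq_len(nh)]
  high_i <- o[(n - nh + 1L):n]
  list(high = mean(reinstatement[high_i], na.rm = TRUE),
       low = mean(reinstatement[low_i], na.rm = TRUE),
       n_half = nh, high_trials = high_i, low_trials = low_i)
}

#' Within-subject 2 x 2 repeated-measures ANOVA
#'
#' Closed-form decomposition for a fully within-subject 2 x 2 design:
#' per-participant contrasts for the two main effects and the interaction,
#' each tested with df = (1, n - 1). A zero-variance contrast with non-zero
#' mean yields an infinite F (flagged via \code{Inf}).
#'
#' @param cells n x 4 matrix of per-participant cell means, columns ordered
#'   A1B1, A1B2, A2B1, A2B2.
#' @return A list with components \code{A}, \code{B}, \code{AB}, each
#'   \code{c(F =, p =)}, plus \code{df = c(1, n - 1)}.
#' @export
rm_anova_2x2 <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4) stop("cells must have 4 columns (A1B1..A2B2)")
  if (anyNA(cells)) stop("missing cells")
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 participants")
  eff <- function(w) {
    cvec <- drop(cells %*% w) / 2
    se <- stats::sd(cvec) / sqrt(n)
    Fv <- if (se == 0) { if (mean(cvec) == 0) 0 else Inf } else
      (mean(cvec) / se)^2
    c(F = Fv, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  }
  list(A = eff(c(1, 1, -1, -1)), B = eff(c(1, -1, 1, -1)),
       AB = eff(c(1, -1, -1, 1)), df = c(1, n - 1))
}

#' Trial-wise cross-band power correlation map (one participant)
#'
#' Pearson correlations, across trials, between band-A power at every time
#' point and band-B power at every time point within a time range, yielding
#' a time x time correlation map.
#'
#' @param tfr A normalized \code{ers_tfr}.
#' @param bandA,bandB c(lo, hi) bands in Hz.
#' @param time_range c(lo, hi) in seconds.
#' @param trials Optional trial indices (default: all); at least 10.
#' @return A list: \code{r} (timeA x timeB correlation matrix) and
#'   \code{times}.
#' @export
crossband_correlation <- function(tfr, bandA, bandB, time_range = c(0.5, 2),
                                  trials = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(tfr$power)[1])
  if (length(trials) < 10) stop("need at least 10 trials")
  ga <- band_timecourse(tfr, bandA, trials)$per_trial
  gb <- band_timecourse(tfr, bandB, trials)$per_trial
  sel <- tfr$times >= time_range[1] - 1e-9 & tfr$times <= time_range[2] + 1e-9
  sel <- sel & !is.na(colSums(ga)) & !is.na(colSums(gb))
  r <- stats::cor(ga[, sel, drop = FALSE], gb[, sel, drop = FALSE])
  list(r = r, times = tfr$times[sel])
}

#' Group-level cross-band correlation test
#'
#' Fisher-z transforms per-participant cross-band correlation maps and tests
#' them against zero with a sign-flip cluster permutation.
#'
#' @param r_maps List of participant correlation matrices (congruent).
#' @inheritParams cluster_permutation_paired
#' @return An \code{ers_clusters} object on the z maps.
#' @export
crossband_group_test <- function(r_maps, alpha_cf = 0.05, n_perm = 1000,
                                 seed = NULL) {
  z <- lapply(r_maps, fisher_z)
  cluster_permutation_paired(z, NULL, alpha_cf = alpha_cf, n_perm = n_perm,
                             seed = seed)
}

#' Across-participant Pearson correlation
#'
#' @param x,y Numeric vectors of per-participant scalars (n >= 3).
#' @return Pearson correlation coefficient.
#' @export
across_participant_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 participants")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}
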