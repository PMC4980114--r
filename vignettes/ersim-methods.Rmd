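---
title: "Quantifying hippocampal pattern completion with ersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal pattern completion with ersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ersim)
```

## The scientific problem

Episodic recollection is thought to rely on *pattern completion*: a partial
retrieval cue reinstates the full neural representation laid down during
encoding, with the hippocampus as the putative auto-associator. With a
single intracranial contact in the anterior hippocampus, the spatial pattern
of activity is not accessible, but the local field potential's
time-frequency content is: each encoding or retrieval event leaves a
"fingerprint" of proportional power changes across frequencies and time.
`ersim` implements the analysis chain that turns single-channel voltage
epochs into evidence for (or against) event-specific reinstatement:

1. epoching and automated artifact rejection,
2. dual-regime spectral decomposition and baseline normalization,
3. sliding-window Spearman correlation of encoding and retrieval patterns
   into trial-wise reinstatement maps,
4. association-matched surrogate maps as the specificity control,
5. cluster-based permutation inference with a minimum-t conjunction,
6. gamma/alpha band power analyses and their linkage to reinstatement.

Because suitable patient recordings cannot be redistributed, the package
includes a first-class synthetic-data module whose output has the
statistical structure the analysis assumes, together with ground truth, so
that every stage can be exercised and validated end to end.

## Spectral decomposition

Power is estimated on a 10-ms grid at 43 frequencies: 2-29 Hz in 1-Hz steps
and 30-100 Hz in 5-Hz steps. The two ranges use different estimators:

* **2-29 Hz**: a Hanning-tapered short-time Fourier estimate with a window
  of five cycles of each frequency (500 ms at 10 Hz, 250 ms at 20 Hz).
  A frequency-adaptive window equalizes the cycle count entering each
  estimate.
* **30-100 Hz**: a multitaper estimate on a fixed 400-ms window with seven
  orthogonal Slepian (DPSS) tapers, giving a spectral smoothing of
  `(K + 1) / (2T) = +/-10 Hz`. Gamma-band power is broadband and benefits
  from the variance reduction.

Windows are centred on the output bin with odd sample counts, and the power
at a grid frequency is read out by evaluating the tapered DFT at exactly
that frequency, not at the nearest FFT bin. Bins whose full window does not
fit inside the epoch are masked invalid rather than imputed. The DPSS
family is computed from the standard symmetric tridiagonal eigenproblem and
is checked in the test suite for orthonormality and spectral concentration
(the test exists because an off-by-one in the off-diagonal produced
plausible-looking but unconcentrated tapers during development; the
symptom was excess cross-trial variance in high-frequency power).

A shortened preset (4 cycles / 200 ms) is available through the
`n_cycles` and `high_window` arguments of `tfr_transform()`.

### Baseline normalization

Power is expressed as proportional change relative to the mean over the
-0.5..0 s pre-stimulus window, per trial and frequency. One subtlety: the
2-Hz estimate uses a 2.5-s window, which never fits inside the pre-stimulus
interval of a -1..+3 s epoch. For such frequencies the baseline is taken
from the earliest *valid* windows spanning the same duration (for 2 Hz
these windows are centred at 0.25 s but still integrate mostly
peri-stimulus signal). This is the package's own choice; alternatives would
be to drop the 2-Hz row or to require longer epochs. A log-power path
(`log_power()`) without any baseline is provided as the control analysis
for pre-stimulus condition differences.

## Reinstatement maps

A representational pattern at time *t* is the 43 x 41 matrix of relative
power in a 400-ms window centred on *t* (variants: frequencies-only 43 x 1,
500-ms 43 x 51, and time-averaged 500-ms 43 x 1). For each trial, every
encoding pattern is correlated with every retrieval pattern using Spearman
rank correlation (average ranks for ties -- ties are possible after
smoothing), yielding an encoding-time x retrieval-time map on the 10-ms
grid. Pattern centres are restricted to times where the pattern window is
valid for *all* 43 frequencies; on the default epoch this gives centres
0.45..1.55 s at both phases, which contains all the windows of interest
(encoding 0.5-1 s, retrieval 1-1.5 s).

The Spearman computation is organised for scale: per trial, all pattern
vectors are rank-transformed in compiled code (a sliding-window sorter that
updates the sort order incrementally as the window advances one bin),
standardized to zero mean and unit norm, and correlated via one BLAS
matrix product per trial pair.

### Surrogate control

Greater AR reinstatement could reflect attention to the (re-presented)
associate rather than event-specific memory. The control correlates each
AR trial's retrieval patterns with the encoding patterns of all *other* AR
trials carrying exactly the same associative target, averaged per trial and
participant. Surrogate pairing is pooled across experimental runs. Because
the map is linear in the (standardized) encoding patterns, the surrogate
average is computed as one matrix product with the summed partner patterns
-- exactly equal to averaging the individual surrogate maps.

Fisher z transforms are applied to the participant-level averaged maps just
before the group test; the trial-level z-then-average alternative differs
by well under 0.01 for |rho| < 0.2 and is available by transforming
trial maps directly.

### Band decomposition of the correlation

`correlation_weights()` decomposes a single pattern-pair correlation into
additive per-frequency contributions: both vectorized patterns are ranked,
standardized so that the mean elementwise product is the correlation, and
the products are summed over the 41 window bins. The weights sum to the
Spearman rho by construction (identity checked to 1e-10 over 1000 random
pairs). `band_restricted_map()` recomputes maps after excluding or keeping
one band, with boundaries delta 2-3, theta 4-7, alpha 8-12, beta 13-29,
gamma1 30-50, gamma2 55-100 Hz; only the alpha and gamma definitions are
fixed by the analyses upstream, the others are conventional.

## Group inference

`cluster_permutation_paired()` computes elementwise paired t statistics
across participants, forms 4-connected clusters of suprathreshold bins
(two-tailed cluster-forming alpha 0.05), sums the t values into a cluster
mass, and compares each observed mass against the permutation null of the
maximum absolute mass under random sign flips of the per-participant
differences (all `2^n` flips when fewer than `n_perm`, else `n_perm`
random draws; p-values use the `(b + 1) / (m + 1)` estimator). Degenerate
bins (zero variance, missing data) are excluded. The conjunction of
AR > IR and AR > surrogate intersects the significant positive cluster
masks of the two contrasts and reports the elementwise minimum t.
`cluster_permutation_F()` provides the omnibus one-way repeated-measures
ANOVA version (AR/IR/M/CR), permuting condition labels within participant.
The permutation count and the 4-neighbour connectivity are package
defaults, chosen conservative and standard; they are recorded in every
result object.

### Linking power to reinstatement

Per-trial gamma (50-90 Hz, 0.5-1.3 s) and alpha (8-12 Hz, 1-2 s) power is
summarized by `cluster_mean_power()`; `median_split_linkage()` splits AR
trials at the participant median (odd trial counts drop the median trial)
and compares windowed reinstatement between halves; the group-level
power (high/low) x band (gamma/alpha) interaction uses the closed-form
within-subject 2 x 2 ANOVA (`rm_anova_2x2()`, validated against
`stats::aov`). Trial-wise gamma-alpha coupling is assessed by
`crossband_correlation()` (Pearson across trials for every time pair,
Fisher z, sign-flip cluster test against zero) and by the
across-participant correlation of windowed band powers.

### Response-locked analyses

To align the analyses with the behavioural response, the stimulus-locked
TFR grid is shifted per trial to the nearest 10-ms bin of the response
latency (`response_lock_tfr()`), inheriting the stimulus-locked
normalization; raw-trace realignment (`response_lock()`) is provided for
completeness. Shifting the decomposed grid avoids re-windowing edge
artifacts; whether the original analyses realigned raw data or TF maps is
not determinable from their description, so the choice is documented here.
Retrieval-side validity becomes trial-specific after realignment; map bins
supported by fewer than half of a condition's trials are dropped, and group
tests exclude bins missing for any participant.

## The synthetic-data generator

`generate_dataset()` emulates the study design: 11 participants; 40 AR, 40
IR, 20 miss and 20 correct-rejection trials by default; 1 kHz sampling of
-1..+3 s stimulus-locked epochs; four associative targets (two colours,
two scenes).

**Background.** Traces are spectrally synthesized 1/f^chi noise
(chi = 2 by default, slope recoverable from the periodogram to +/-0.3)
plus weak theta/alpha/gamma band bumps, scaled to 25 uV. The power law is
floored below 1 Hz: without that floor, sub-hertz drift carries orders of
magnitude more power than the gamma band and leaks through taper sidelobes
into every estimate -- real recordings are hardware high-passed, so the
floor emulates the acquisition chain.

**Fingerprints.** Every old trial receives a trial-unique smooth
frequency x time envelope (log-amplitude field with 7 x 4 knots, contrast
1.4) realised as amplitude-modulated cosines at the 43 grid frequencies
inside the 0.5-1 s encoding window. AR trials -- and only AR trials --
receive an amplitude-modulated copy of their own envelope in the 1-1.5 s
retrieval window. Two constraints make the planted patterns behave like
the phenomenon the analysis targets. First, the per-frequency component
amplitudes track the background power inside each spectral estimator's
equivalent bandwidth, so the fingerprint produces proportional power
changes of comparable size at every analysed frequency -- reinstatement
draws on the whole spectrum rather than being carried by the bands where
1/f background is weakest. Second, the envelope's energy inside each
analysis-aligned band is fixed at every time slice: band-mean power in
any window carries no incidental envelope variability, so the
power/reinstatement linkage analyses see only the explicitly planted
coupling (trial identity lives in the within-band spectral profile).
Without this constraint, trials with incidentally gamma-heavy or
front-loaded envelopes both measure higher gamma power and reinstate
better, a mechanical confound of the median-split analysis; a small
residual coupling (per-participant |r| of order 0.1) remains because the
spectral estimators smooth across normalization boundaries, and the null
calibration accounts for it. The envelope mixes an association-shared and a
trial-unique component (`mixing_weight` 0.3), so same-associate trials are
more similar than cross-associate trials but less similar than a trial to
itself -- the structure the surrogate control exists to remove. The
fingerprint amplitude (0.45 of background SD) was calibrated once so that
the recovered AR own-map correlation in the window of interest is about
0.05, the scale reported for hippocampal reinstatement; the magnitude of
true event-specific similarity is not otherwise constrained by published
values.

**Band effects and coupling.** AR retrieval trials carry a 50-90 Hz burst
at 0.5-1.3 s and IR trials an 8-12 Hz burst at 1-2 s. Amplitudes are
expressed relative to the background SD within the band (defaults 0.9 for
gamma, 2.8 for alpha); the alpha default is large in proportional-power
terms because single-channel alpha estimates are noisy (few independent
time-frequency samples in the 1-2 s window) and because the reinstated
fingerprint itself contributes alpha-band power to AR trials, which the
IR effect must clear -- the defaults are chosen so the planted contrasts
are detectable at strengths comparable to the reported group statistics.
A per-trial "retrieval strength" modulator ties the analyses together the
way the phenomenon is described: it scales the reinstated fingerprint and
the gamma burst up, and the AR alpha components down. High-gamma trials
therefore genuinely reinstate more and show less alpha -- the linkage the
median-split and cross-band analyses should recover, with `coupling = 0`
as the null. Response latencies are shifted truncated log-normals (AR mean
1.91 s, IR 2.14 s, trial SD 0.45 s, limit 5 s), giving the faster AR
responses the response-locked analyses rely on.

**Artifacts.** With probability 0.12 per trial a damped alternating spike
(8 trial-SD) is injected, exceeding both the amplitude and the gradient
threshold of the rejection rule (`median + 3 IQR` of all pooled values,
joint exceedance at the same time point required). On artifact-free
correlated-noise trials the rule's intrinsic false-alarm rate is about 1%
per trial, so recovered rejection fractions run slightly above the planted
rate -- consistent with an automated rule that also catches chance
excursions.

**What the generator does not emulate:** volume conduction, epileptiform
activity beyond simple transients, non-stationary background spectra,
serial dependencies between trials, or multi-contact geometry. Passing the
recovery suite therefore shows that the analysis chain detects effects of
the assumed form at realistic sizes -- not that real hippocampal data
contain them.

## Problem sizes and runtime choices

The recovery suite runs the full pipeline on 20 seeds of the default
11-participant, 40 AR / 40 IR design at the default 1000 permutations per
cluster test (under a minute per seed); near-threshold cluster p-values
are estimator-noise-limited at substantially reduced permutation counts,
so reduced draws are only used for exploratory runs. The type-I
calibration uses 200
null simulations at 500 permutations on 25 x 25 maps with n = 11. The TFR
is computed over -0.5..2.5 s for the analyses (full epoch available via
`t_range = NULL`). The acceptance script reports recovery over 6 seeds
and 100 null simulations. These sizes are the package's defaults for
simulation studies; all of them scale linearly in trials, participants and
permutations.

## Known limitations

* Reinstatement is single-channel by design; cross-channel or decoding
  reinstatement is out of scope.
* The 2-Hz row's baseline is peri-stimulus (see above); analyses that
  depend critically on delta-band baselines should use longer epochs.
* Response-locked maps lose bins whose source windows fall outside the
  valid stimulus-locked range for a given latency; with slow responses the
  late retrieval axis thins out.
* Cluster-level inference licenses statements about clusters, not about
  individual bins; reported windows describe cluster extent.
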