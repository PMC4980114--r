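# small relative-power TFR with enough time bins for 400/500-ms patterns
rand_tfr <- function(n_trials, seed = 1, nf = 43, times = seq(0, 2, 0.01),
                     events = NULL) {
  set.seed(seed)
  toy_tfr(array(rexp(n_trials * nf * length(times)) + 0.05,
                c(n_trials, nf, length(times))),
          freqs = frequency_grid()$freq[seq_len(nf)], times = times,
          events = events)
}

test_that("patterns have the documented shapes", {
  tfr <- rand_tfr(1)
  c0 <- pattern_centres(tfr, "tf_400ms")[1]
  expect_equal(dim(extract_pattern(tfr, 1, c0, "tf_400ms")), c(43, 41))
  c5 <- pattern_centres(tfr, "tf_500ms")[1]
  expect_equal(dim(extract_pattern(tfr, 1, c5, "tf_500ms")), c(43, 51))
  expect_equal(dim(extract_pattern(tfr, 1, c5, "freqs_only")), c(43, 1))
  # avg_500ms of a constant tfr is a constant 43-vector
  ctf <- toy_tfr(array(2.5, c(1, 43, 201)), frequency_grid()$freq,
                 seq(0, 2, 0.01))
  expect_equal(as.vector(extract_pattern(ctf, 1, 1, "avg_500ms")),
               rep(2.5, 43))
  expect_error(extract_pattern(tfr, 1, 0.05, "tf_400ms"), "out of the valid")
})

test_that("pattern centres respect the validity mask", {
  valid <- matrix(TRUE, 43, 201)
  valid[1, 1:30] <- FALSE      # 2 Hz invalid early
  tfr <- rand_tfr(1)
  tfr$valid <- valid
  ctr <- pattern_centres(tfr, "tf_400ms")
  # centres need 20 bins margin beyond the last invalid 2-Hz bin
  expect_equal(min(ctr), tfr$times[31] + 0.2)
  expect_equal(max(ctr), tfr$times[201] - 0.2)
})

test_that("a trial correlated with itself gives a unit diagonal", {
  tfr <- rand_tfr(1, seed = 3)
  m <- reinstatement_map(tfr, tfr, 1, 1)
  expect_equal(unname(diag(unclass(m))), rep(1, nrow(m)), tolerance = 1e-12)
  expect_true(all(m[!is.na(m)] <= 1 + 1e-12 & m[!is.na(m)] >= -1 - 1e-12))
})

test_that("swapping encoding and retrieval transposes the map", {
  e <- rand_tfr(1, seed = 4)
  r <- rand_tfr(1, seed = 5)
  m1 <- reinstatement_map(e, r, 1, 1)
  m2 <- reinstatement_map(r, e, 1, 1)
  expect_equal(unclass(m1), t(unclass(m2)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sliding Spearman equals the rank-then-Pearson oracle", {
  # toy 5 x 3 patterns with ties, against cor(method = "spearman")
  set.seed(6)
  nf <- 5
  times <- seq(0, 0.2, 0.01)
  pe <- array(sample(1:8, nf * 21, TRUE) / 4, c(1, nf, 21))
  pr <- array(sample(1:8, nf * 21, TRUE) / 4, c(1, nf, 21))
  fe <- toy_tfr(pe, c(8, 10, 12, 40, 60), times)
  fr <- toy_tfr(pr, c(8, 10, 12, 40, 60), times)
  # freqs_only: pattern at centre t is the nf-vector at that bin
  m <- reinstatement_map(fe, fr, 1, 1, variant = "freqs_only")
  for (i in c(1, 5, 11, 21)) for (j in c(2, 7, 14)) {
    oracle <- suppressWarnings(
      cor(pe[1, , i], pr[1, , j], method = "spearman"))
    expect_equal(unclass(m)[i, j], oracle, tolerance = 1e-12)
  }
  # tf variant against explicit vectorized-window oracle
  tfr_e <- rand_tfr(1, seed = 7)
  tfr_r <- rand_tfr(1, seed = 8)
  m2 <- reinstatement_map(tfr_e, tfr_r, 1, 1)
  ctr <- pattern_centres(tfr_e, "tf_400ms")
  pick <- c(1, 25, 80)
  for (i in pick) for (j in pick) {
    ve <- as.vector(extract_pattern(tfr_e, 1, ctr[i]))
    vr <- as.vector(extract_pattern(tfr_r, 1, ctr[j]))
    oracle <- cor(rank(ve), rank(vr))
    expect_equal(unclass(m2)[i, j], oracle, tolerance = 1e-12)
  }
})

test_that("independent patterns give correlations centred on zero", {
  set.seed(9)
  vals <- replicate(200, {
    e <- rnorm(60); r <- rnorm(60)
    cor(rank(e), rank(r))
  })
  tfr_e <- rand_tfr(20, seed = 10)
  tfr_r <- rand_tfr(20, seed = 11)
  ms <- vapply(1:20, function(i)
    mean(unclass(reinstatement_map(tfr_e, tfr_r, i, i))), numeric(1))
  expect_lt(abs(mean(ms)), 2 * sd(ms) / sqrt(20) + 0.01)
})

test_that("condition averaging is linear and order invariant", {
  tfr <- rand_tfr(4, seed = 12)
  maps <- lapply(1:4, function(i) reinstatement_map(tfr, tfr, i, (i %% 4) + 1))
  expect_equal(unclass(condition_average(maps[1])), unclass(maps[[1]]),
               ignore_attr = TRUE)
  m <- maps[[1]]
  neg <- -unclass(m)
  attr_copy <- m; attr_copy[] <- neg
  avg <- condition_average(list(m, attr_copy))
  expect_true(all(abs(avg) < 1e-12))
  a1 <- condition_average(maps)
  a2 <- condition_average(maps[c(3, 1, 4, 2)])
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-12)
})

test_that("surrogates equal the own map when all trials are identical", {
  ev <- toy_events(n_ar = 4, n_ir = 0)
  ev$association <- "blue"
  base <- rand_tfr(1, seed = 13)
  pow <- array(rep(base$power[1, , ], each = 4), c(4, 43, 201))
  tfr <- toy_tfr(pow, base$freqs, base$times, events = ev)
  pr <- participant_reinstatement(tfr, tfr, conditions = "AR")
  expect_equal(unclass(pr$AR_surrogate), unclass(pr$AR), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("surrogate maps sit below own maps for trial-unique patterns", {
  # group-level property: the own-trial map exceeds the association-matched
  # surrogate in the planted window on average (single participants at this
  # trial count are too noisy for a deterministic sign)
  cfg <- study_config(n_participants = 3,
                      n_trials = c(AR = 40, IR = 1, M = 0, CR = 0),
                      artifact_rate = 0, seed = 14)
  ds <- generate_dataset(cfg)
  gaps <- vapply(1:3, function(p) {
    tfe <- baseline_normalize(tfr_transform(
      ds$encoding[ds$encoding$events$participant == p],
      t_range = c(-0.5, 2.5)))
    tfr <- baseline_normalize(tfr_transform(
      ds$retrieval[ds$retrieval$events$participant == p],
      t_range = c(-0.5, 2.5)))
    pr <- participant_reinstatement(tfe, tfr, conditions = "AR",
                                    window = list(enc = c(0.5, 1),
                                                  ret = c(1, 1.5)))
    map_window_mean(pr$AR, c(0.5, 1), c(1, 1.5)) -
      map_window_mean(pr$AR_surrogate, c(0.5, 1), c(1, 1.5))
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gte(sum(gaps > 0), 2)
})

test_that("band restriction reduces to the reference map at the extremes", {
  e <- rand_tfr(1, seed = 15)
  r <- rand_tfr(1, seed = 16)
  ref <- reinstatement_map(e, r, 1, 1)
  # "exclude" a band outside the grid keeps every row
  allin <- band_restricted_map(e, r, 1, 1, band = c(150, 200),
                               mode = "exclude")
  expect_equal(unclass(allin), unclass(ref), tolerance = 1e-12)
  only_all <- band_restricted_map(e, r, 1, 1, band = c(2, 100),
                                  mode = "only")
  expect_equal(unclass(only_all), unclass(ref), tolerance = 1e-12)
  # excluding a named band changes the map but keeps it a correlation
  excl <- band_restricted_map(e, r, 1, 1, band = "gamma1")
  expect_false(isTRUE(all.equal(unclass(excl), unclass(ref))))
  expect_true(all(abs(excl[!is.na(excl)]) <= 1 + 1e-12))
  expect_error(band_restricted_map(e, r, 1, 1, band = c(150, 200),
                                   mode = "only"), "empty")
})

test_that("correlation weights sum to the Spearman coefficient", {
  set.seed(17)
  # identical patterns: weights sum to 1
  p <- matrix(rnorm(43 * 41), 43)
  expect_equal(sum(correlation_weights(p, p)), 1, tolerance = 1e-12)
  # rank-reversed patterns: weights sum to -1
  q <- matrix(-as.vector(p), 43)
  expect_equal(sum(correlation_weights(p, q)), -1, tolerance = 1e-12)
  # toy 4 x 3 pair against the direct Spearman
  a <- matrix(sample(12) / 3, 4)
  b <- matrix(sample(12) / 3, 4)
  w <- correlation_weights(a, b)
  expect_length(w, 4)
  expect_equal(sum(w), cor(as.vector(a), as.vector(b), method = "spearman"),
               tolerance = 1e-10)
  expect_error(correlation_weights(matrix(1, 4, 3), b), "constant")
})

test_that("fisher z is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_equal(z, atanh(1 - 1e-6))
  expect_true(is.na(fisher_z(NA)))
})

test_that("windowed map means use the declared time axes", {
  m <- matrix(1:12, 3, 4)
  map <- ersim:::.new_map(m, enc_times = c(0.5, 0.6, 0.7),
                          ret_times = c(1, 1.1, 1.2, 1.3))
  expect_equal(map_window_mean(map, c(0.5, 0.6), c(1, 1.1)),
               mean(m[1:2, 1:2]))
  expect_error(map_window_mean(map, c(2, 3), c(1, 1.1)), "outside")
})
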