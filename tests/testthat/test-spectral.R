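fs <- 1000
t_axis <- seq(-1, 3, by = 1 / fs)

test_that("zero signal gives zero power everywhere valid", {
  ep <- epoch_set(matrix(0, 2, length(t_axis)), t_axis, fs, "stimulus")
  tf <- tfr_transform(ep, t_range = c(-0.5, 2))
  expect_true(all(tf$power[, , ][!is.na(tf$power)] == 0))
  expect_true(all(is.na(tf$power[1, 1, !tf$valid[1, ]])))
})

test_that("a pure sinusoid peaks at its own frequency bin", {
  for (f0 in c(10, 23, 60)) {
    ep <- epoch_set(matrix(sin(2 * pi * f0 * t_axis), 1), t_axis, fs,
                    "stimulus")
    tf <- tfr_transform(ep, t_range = c(0.5, 1.5))
    for (j in seq_along(tf$times)) {
      v <- tf$power[1, , j]
      v[!tf$valid[, j]] <- NA
      expect_equal(tf$freqs[which.max(v)], f0)
    }
  }
})

test_that("power matches a direct tapered DFT oracle", {
  set.seed(44)
  x <- rnorm(length(t_axis))
  ep <- epoch_set(matrix(x, 1), t_axis, fs, "stimulus")
  tf <- tfr_transform(ep)
  i <- which(abs(tf$times - 1.0) < 1e-9)
  # multitaper oracle at 40 Hz: mean over tapers of |sum v x exp(-2pi i f t)|^2
  L <- 401; h <- 200
  s <- which(abs(t_axis - 1.0) < 1e-9)
  seg <- x[(s - h):(s + h)]
  tt <- (seq_len(L) - (L + 1) / 2) / fs
  V <- dpss_tapers(L, 10 / fs, 7)
  oracle_mt <- mean(vapply(1:7, function(m)
    Mod(sum(V[, m] * seg * exp(-2i * pi * 40 * tt)))^2, numeric(1)))
  mine <- tf$power[1, which(tf$freqs == 40), i]
  expect_lt(abs(mine - oracle_mt) / oracle_mt, 1e-10)
  # Hanning oracle at 10 Hz: 5 cycles = 501 samples
  L2 <- 501; h2 <- 250
  seg2 <- x[(s - h2):(s + h2)]
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L2 - 1) / (L2 - 1))
  w <- w / sqrt(sum(w^2))
  tt2 <- (seq_len(L2) - (L2 + 1) / 2) / fs
  oracle_h <- Mod(sum(w * seg2 * exp(-2i * pi * 10 * tt2)))^2
  mine2 <- tf$power[1, which(tf$freqs == 10), i]
  expect_lt(abs(mine2 - oracle_h) / oracle_h, 1e-10)
})

test_that("unit sinusoid power is stationary across time bins", {
  ep <- epoch_set(matrix(sin(2 * pi * 10 * t_axis), 1), t_axis, fs,
                  "stimulus")
  tf <- tfr_transform(ep, t_range = c(0, 2))
  p <- tf$power[1, which(tf$freqs == 10), ]
  expect_lt(max(p) - min(p), 1e-8 * mean(p))
})

test_that("the valid-time mask is symmetric for matched margins", {
  ep <- epoch_set(matrix(rnorm(length(t_axis)), 1), t_axis, fs, "stimulus")
  tf <- tfr_transform(ep)
  # epoch -1..3, centred grid: validity margins mirror around 1.0 s
  for (j in seq_along(tf$freqs)) {
    v <- tf$valid[j, ]
    expect_identical(v, rev(v))
  }
  # 2 Hz (2.5 s window) valid exactly on 0.25..1.75
  expect_equal(range(tf$times[tf$valid[1, ]]), c(0.25, 1.75))
})

test_that("hanning/multitaper regimes join smoothly on broadband noise", {
  set.seed(12)
  ep <- background_epochs(40, seed = 12)
  tf <- tfr_transform(ep, t_range = c(0.5, 1.5))
  m29 <- mean(tf$power[, which(tf$freqs == 29), ])
  m30 <- mean(tf$power[, which(tf$freqs == 30), ])
  expect_lt(abs(10 * log10(m29 / m30)), 3)
})

test_that("baseline normalization produces unit-mean baselines", {
  set.seed(13)
  ep <- background_epochs(6, seed = 13)
  tf <- tfr_transform(ep, t_range = c(-0.5, 2))
  rel <- baseline_normalize(tf)
  expect_identical(rel$normalization, "relative")
  for (j in c(5, 20, 40)) {   # frequencies with valid baseline bins
    bins <- rel$valid[j, ] & rel$times >= -0.5 & rel$times <= 0
    if (!any(bins)) next
    expect_equal(rowMeans(rel$power[, j, bins, drop = FALSE]),
                 rep(1, 6), tolerance = 1e-12)
  }
  # constant tfr equals its baseline everywhere -> all ones
  cpow <- array(3, c(2, 3, 101))
  ctf <- toy_tfr(cpow, c(8, 10, 12), seq(-0.5, 0.5, 0.01),
                 normalization = "raw")
  crel <- baseline_normalize(ctf)
  expect_true(all(crel$power == 1))
  # doubled post-stimulus power -> exactly 2
  cpow2 <- cpow
  cpow2[, , 52:101] <- 6
  crel2 <- baseline_normalize(toy_tfr(cpow2, c(8, 10, 12),
                                      seq(-0.5, 0.5, 0.01),
                                      normalization = "raw"))
  expect_true(all(crel2$power[, , 60:101] == 2))
})

test_that("frequencies without valid baseline bins use the fallback", {
  set.seed(14)
  ep <- background_epochs(4, seed = 14)
  tf <- tfr_transform(ep)          # full grid: 2 Hz valid only from 0.25 s
  expect_error(baseline_normalize(tf, fallback = FALSE), "2 Hz")
  rel <- baseline_normalize(tf)
  # fallback uses the earliest valid 2-Hz bins; their mean is 1
  bins <- utils::head(which(rel$valid[1, ]), 51)
  expect_equal(rowMeans(rel$power[, 1, bins]), rep(1, 4),
               tolerance = 1e-12)
})

test_that("log power is the elementwise log and relates to relative power", {
  pow <- array(exp(seq_len(24)), c(2, 3, 4))
  tf <- toy_tfr(pow, c(8, 10, 12), seq(0, 0.03, 0.01),
                normalization = "raw")
  lg <- log_power(tf)
  expect_equal(lg$power, log(pow))
  expect_identical(lg$normalization, "log")
  # log(relative) = log(raw) - log(baseline mean), per trial and frequency
  set.seed(15)
  pow2 <- array(rexp(2 * 3 * 101) + 0.1, c(2, 3, 101))
  tf2 <- toy_tfr(pow2, c(8, 10, 12), seq(-0.5, 0.5, 0.01),
                 normalization = "raw")
  rel <- baseline_normalize(tf2)
  lg2 <- log_power(tf2)
  bl <- apply(pow2[, , 1:51], c(1, 2), mean)
  for (i in 1:2) for (j in 1:3)
    expect_equal(log(rel$power[i, j, ]), lg2$power[i, j, ] - log(bl[i, j]),
                 tolerance = 1e-12)
  neg <- toy_tfr(array(c(-1, rep(1, 11)), c(1, 3, 4)), c(8, 10, 12),
                 seq(0, 0.03, 0.01), normalization = "raw")
  expect_error(log_power(neg), "positive")
})

test_that("band time courses average the right bins", {
  pow <- array(0, c(3, 4, 5))
  for (j in 1:4) pow[, j, ] <- j
  tf <- toy_tfr(pow, c(8, 10, 40, 60), seq(0, 0.04, 0.01))
  # band covering the full grid equals the global mean
  bt <- band_timecourse(tf, c(2, 100))
  expect_equal(unname(bt$mean), rep(2.5, 5))
  # single-bin band returns that bin's course
  bt1 <- band_timecourse(tf, c(40, 40))
  expect_equal(unname(bt1$mean), rep(3, 5))
  expect_error(band_timecourse(tf, c(200, 300)), "does not intersect")
})

test_that("cluster mean power agrees with hand summation", {
  pow <- array(seq_len(3 * 3 * 3), c(3, 3, 3))
  tf <- toy_tfr(pow, c(10, 20, 30), c(0, 0.01, 0.02))
  # constant map returns the constant
  cm <- cluster_mean_power(toy_tfr(array(7, c(2, 3, 3)), c(10, 20, 30),
                                   c(0, 0.01, 0.02)),
                           c(10, 30), c(0, 0.02))
  expect_equal(cm, c(7, 7))
  # single-bin mask returns that bin
  msk <- matrix(FALSE, 3, 3); msk[2, 3] <- TRUE
  expect_equal(cluster_mean_power(tf, mask = msk), pow[, 2, 3])
  # 3 x 3 window vs hand sum for trial 2
  hand <- mean(pow[2, , ])
  expect_equal(cluster_mean_power(tf, c(10, 30), c(0, 0.02))[2], hand)
  expect_error(cluster_mean_power(tf, c(50, 60), c(0, 0.02)), "empty mask")
})
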