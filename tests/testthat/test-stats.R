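test_that("component labelling is 4-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- TRUE          # diagonal: two components
  lab <- label_components(m)
  expect_identical(max(lab), 2L)
  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2:4] <- TRUE; m2[3, 4] <- TRUE # L-shape: one component
  expect_identical(max(label_components(m2)), 1L)
  expect_identical(label_components(matrix(FALSE, 3, 3)),
                   matrix(0L, 3, 3))
})

test_that("identical condition maps give an empty cluster result", {
  set.seed(1)
  x <- array(rnorm(8 * 10 * 10), c(8, 10, 10))
  res <- cluster_permutation_paired(x, x, n_perm = 100, seed = 1)
  expect_length(res$clusters, 0)
})

test_that("a planted block offset is recovered with small p", {
  set.seed(2)
  n <- 11
  x <- array(rnorm(n * 40 * 40), c(n, 40, 40))
  y <- array(rnorm(n * 40 * 40), c(n, 40, 40))
  pooled_sd <- sqrt(2)
  x[, 11:30, 11:30] <- x[, 11:30, 11:30] + 5 * pooled_sd
  res <- cluster_permutation_paired(x, y, n_perm = 1000, seed = 3)
  expect_gte(length(res$clusters), 1)
  top <- res$clusters[[1]]
  expect_lte(top$p, 0.002)
  expect_identical(top$sign, 1)
  inblock <- matrix(FALSE, 40, 40); inblock[11:30, 11:30] <- TRUE
  expect_gt(sum(top$mask & inblock) / sum(inblock), 0.9)
})

test_that("cluster masses equal the sum of their bins", {
  set.seed(4)
  x <- array(rnorm(6 * 15 * 15), c(6, 15, 15))
  x[, 4:8, 4:8] <- x[, 4:8, 4:8] + 2
  res <- cluster_permutation_paired(x, NULL, n_perm = 50, seed = 5)
  for (cl in res$clusters)
    expect_equal(cl$mass, sum(res$stat[cl$mask]), tolerance = 1e-12)
})

test_that("permutation p-values respect paired-test symmetry and seeding", {
  set.seed(6)
  x <- array(rnorm(7 * 12 * 12), c(7, 12, 12))
  y <- array(rnorm(7 * 12 * 12), c(7, 12, 12))
  r1 <- cluster_permutation_paired(x, y, n_perm = 200, seed = 7)
  r2 <- cluster_permutation_paired(y, x, n_perm = 200, seed = 7)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p"),
               vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_equal(r1$stat, -r2$stat)
  r3 <- cluster_permutation_paired(x, y, n_perm = 200, seed = 7)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r3$clusters, `[[`, numeric(1), "p"))
  expect_identical(r1$null_max, r3$null_max)
})

test_that("small cohorts enumerate all sign flips", {
  set.seed(8)
  x <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  res <- cluster_permutation_paired(x, NULL, n_perm = 1000, seed = 9)
  expect_identical(res$n_perm, 32L)
})

test_that("degenerate bins are excluded from clustering", {
  set.seed(10)
  x <- array(rnorm(6 * 9 * 9), c(6, 9, 9))
  x[, 3, 3] <- 1                       # zero variance bin
  x[, 4, 4] <- NA
  res <- cluster_permutation_paired(x, NULL, n_perm = 50, seed = 1)
  expect_true(is.na(res$stat[3, 3]))
  expect_true(is.na(res$stat[4, 4]))
  for (cl in res$clusters) {
    expect_false(cl$mask[3, 3])
    expect_false(cl$mask[4, 4])
  }
})

test_that("min-t conjunction intersects significant positive clusters", {
  set.seed(11)
  n <- 10
  base <- array(rnorm(n * 20 * 20, sd = 0.3), c(n, 20, 20))
  eff1 <- base; eff1[, 3:8, 3:8] <- eff1[, 3:8, 3:8] + 2
  eff2 <- base + array(rnorm(n * 400, sd = 0.3), c(n, 20, 20))
  eff2[, 14:19, 14:19] <- eff2[, 14:19, 14:19] + 2
  rA <- cluster_permutation_paired(eff1, NULL, n_perm = 200, seed = 12)
  rB <- cluster_permutation_paired(eff2, NULL, n_perm = 200, seed = 13)
  cj <- conjunction_min_t(rA, rB)
  # disjoint effects: empty conjunction
  expect_false(any(cj$mask[3:8, 3:8] & cj$mask[14:19, 14:19]))
  # self-conjunction: mask = significant clusters, min-t = t map
  cjs <- conjunction_min_t(rA, rA)
  expect_identical(cjs$mask, significant_mask(rA))
  expect_equal(cjs$min_t[cjs$mask], rA$stat[cjs$mask])
  expect_true(all(is.na(cjs$min_t[!cjs$mask])))
  # conjunction mask is contained in each parent mask
  expect_true(all(!cj$mask | significant_mask(rA)))
  expect_true(all(!cj$mask | significant_mask(rB)))
})

test_that("RM-ANOVA F map matches the aov oracle and finds condition effects", {
  # oracle check on a single bin, n = 5, k = 4
  set.seed(14)
  vals <- matrix(rnorm(20), 5, 4)
  x <- array(vals, c(5, 4, 1, 1))
  res <- cluster_permutation_F(x, n_perm = 20, seed = 15)
  df <- data.frame(y = as.vector(vals),
                   subj = factor(rep(1:5, 4)),
                   cond = factor(rep(1:4, each = 5)))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  f_oracle <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$stat[1, 1], f_oracle, tolerance = 1e-10)
  # identical conditions: empty result
  same <- array(rep(rnorm(6 * 64), 4), c(6, 64, 4))
  same <- aperm(array(same, c(6, 8, 8, 4)), c(1, 4, 2, 3))
  expect_length(cluster_permutation_F(same, n_perm = 30,
                                      seed = 16)$clusters, 0)
  # effect confined to one condition is recovered with ordered means
  set.seed(17)
  arr <- array(rnorm(11 * 4 * 12 * 12, sd = 1), c(11, 4, 12, 12))
  arr[, 2, 4:9, 4:9] <- arr[, 2, 4:9, 4:9] + 2.5
  resF <- cluster_permutation_F(arr, n_perm = 200, seed = 18)
  expect_gte(length(resF$clusters), 1)
  expect_lt(resF$clusters[[1]]$p, 0.05)
  msk <- resF$clusters[[1]]$mask
  cellmeans <- vapply(1:4, function(c)
    mean(apply(arr[, c, , ], 1, function(m) mean(m[msk]))), numeric(1))
  expect_identical(which.max(cellmeans), 2L)
})

test_that("2x2 within-subject ANOVA matches aov and handles edge cases", {
  # all cells equal: F = 0
  eq <- matrix(3, 5, 4)
  r0 <- rm_anova_2x2(eq)
  expect_equal(unname(r0$AB["F"]), 0)
  # noiseless crossed interaction: infinite F flagged
  d <- c(1, -1, -1, 1)
  crossed <- matrix(rep(d, each = 4), 4)
  expect_identical(unname(rm_anova_2x2(crossed)$AB[["F"]]), Inf)
  # noisy 2x2 against the aov oracle (n = 4)
  set.seed(19)
  cells <- matrix(rnorm(16, mean = rep(c(2, 1, 1, 2), each = 4)), 4)
  r <- rm_anova_2x2(cells)
  df <- data.frame(y = as.vector(cells),
                   subj = factor(rep(1:4, 4)),
                   A = factor(rep(c(1, 1, 2, 2), each = 4)),
                   B = factor(rep(c(1, 2, 1, 2), each = 4)))
  fit <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = df))
  expect_equal(unname(r$A[["F"]]),
               fit[["Error: subj:A"]][[1]]["A", "F value"],
               tolerance = 1e-10)
  expect_equal(unname(r$B[["F"]]),
               fit[["Error: subj:B"]][[1]]["B", "F value"],
               tolerance = 1e-10)
  expect_equal(unname(r$AB[["F"]]),
               fit[["Error: subj:A:B"]][[1]]["A:B", "F value"],
               tolerance = 1e-10)
  # pure main-effect pattern: interaction contrast exactly zero -> F = 0
  main <- matrix(rep(c(2, 2, 1, 1), each = 4), 4)
  expect_equal(unname(rm_anova_2x2(main)$AB[["F"]]), 0)
  expect_error(rm_anova_2x2(cells[, 1:3]), "4 columns")
  expect_error(rm_anova_2x2({cells[1, 1] <- NA; cells}), "missing")
})

test_that("median split partitions at the median and drops the middle", {
  r <- median_split_linkage(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$high, 3.5)
  expect_equal(r$low, 1.5)
  r5 <- median_split_linkage(c(5, 1, 3, 2, 4), c(50, 10, 30, 20, 40))
  expect_equal(r5$n_half, 2L)
  expect_equal(r5$high, 45)            # median trial (3) excluded
  expect_equal(r5$low, 15)
  expect_error(median_split_linkage(rep(1, 6), rnorm(6)), "equal")
  expect_error(median_split_linkage(1:3, 1:3), "at least 4")
})

test_that("median split tracks planted coupling and is null without it", {
  set.seed(20)
  hits <- c(coupled = 0, null = 0)
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    latent <- rnorm(24)
    power <- latent + rnorm(24, sd = 0.5)
    reinst_c <- 0.05 + 0.03 * latent + rnorm(24, sd = 0.02)
    reinst_0 <- 0.05 + rnorm(24, sd = 0.03)
    rc <- median_split_linkage(power, reinst_c)
    r0 <- median_split_linkage(power, reinst_0)
    hits["coupled"] <- hits["coupled"] + (rc$high > rc$low)
    hits["null"] <- hits["null"] + (r0$high > r0$low)
  }
  expect_gte(hits[["coupled"]] / n_rep, 0.9)
  expect_gte(hits[["null"]] / n_rep, 0.25)
  expect_lte(hits[["null"]] / n_rep, 0.75)
})

test_that("cross-band correlation maps have the expected structure", {
  set.seed(21)
  nt <- 30
  trials <- 40
  pow <- array(rexp(trials * 4 * nt) + 0.1, c(trials, 4, nt))
  tfr <- toy_tfr(pow, c(8, 10, 50, 60), seq(0.5, by = 0.01,
                                            length.out = nt))
  cb <- crossband_correlation(tfr, c(8, 10), c(8, 10),
                              time_range = c(0.5, 0.79))
  expect_equal(unname(diag(cb$r)), rep(1, nt), tolerance = 1e-12)
  # independent bands: correlations centred on zero
  cb2 <- crossband_correlation(tfr, c(8, 10), c(50, 60),
                               time_range = c(0.5, 0.79))
  expect_lt(abs(mean(cb2$r)), 0.1)
  expect_error(crossband_correlation(tfr, c(8, 10), c(50, 60),
                                     trials = 1:5), "at least 10")
})

test_that("across-participant correlation is plain Pearson", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(across_participant_correlation(x, 2 * x), 1)
  expect_equal(across_participant_correlation(x, -x), -1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(across_participant_correlation(x, y), cor(x, y))
  expect_error(across_participant_correlation(x, rep(1, 5)), "zero variance")
  expect_error(across_participant_correlation(1:2, 1:2), "at least 3")
})

test_that("cluster tables and map plots summarise results faithfully", {
  set.seed(22)
  x <- array(rnorm(8 * 15 * 20), c(8, 15, 20))
  x[, 4:9, 6:12] <- x[, 4:9, 6:12] + 2
  res <- cluster_permutation_paired(x, NULL, n_perm = 100, seed = 23)
  fx <- seq(2, 30, 2); ty <- seq(0, 1.9, 0.1)
  tab <- cluster_table(res, fx, ty)
  expect_identical(nrow(tab), length(res$clusters))
  expect_equal(tab$mass[1], res$clusters[[1]]$mass)
  expect_true(all(diff(abs(tab$mass)) <= 0))
  # bounding box of the top cluster contains the planted block
  expect_lte(tab$x_lo[1], fx[4]); expect_gte(tab$x_hi[1], fx[9])
  expect_lte(tab$y_lo[1], ty[6]); expect_gte(tab$y_hi[1], ty[12])
  same <- array(rnorm(8 * 36), c(8, 6, 6))
  empty <- cluster_table(cluster_permutation_paired(same, same,
                                                    n_perm = 20, seed = 1))
  expect_identical(nrow(empty), 0L)
  # plot methods draw without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(res, fx, ty))
  m <- ersim:::.new_map(matrix(runif(25, -0.1, 0.1), 5),
                        enc_times = seq(0.5, 0.9, 0.1),
                        ret_times = seq(1, 1.4, 0.1))
  expect_silent(plot(m, mask = matrix(c(TRUE, rep(FALSE, 24)), 5)))
})
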