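#' Label 4-connected components of a logical matrix
#'
#' Foreground bins are treated as graph vertices with edges between
#' 4-neighbours; connected components are labelled 1..k (0 = background).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  k <- length(idx)
  if (!k) return(out)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(k)
  okd <- (idx %% nr) != 0L              # has a neighbour below
  okd[okd] <- mask[idx[okd] + 1L]
  okr <- idx + nr <= nr * nc            # has a neighbour to the right
  okr[okr] <- mask[idx[okr] + nr]
  edges <- c(rbind(pos[idx[okd]], pos[idx[okd] + 1L]),
             rbind(pos[idx[okr]], pos[idx[okr] + nr]))
  g <- igraph::make_graph(edges, n = k, directed = FALSE)
  out[idx] <- as.integer(igraph::components(g)$membership)
  out
}

# maximum absolute signed cluster mass of a statistic matrix thresholded at
# +/- thr (both signs jointly); 0 when nothing is suprathreshold
.max_cluster_mass <- function(stat, thr, excl) {
  mx <- 0
  for (sgn in c(1, -1)) {
    m <- !excl & !is.na(stat) & sgn * stat > thr
    if (!any(m)) next
    lab <- label_components(m)
    masses <- abs(rowsum(stat[m], lab[m]))
    mx <- max(mx, masses)
  }
  mx
}

# observed signed clusters: list of (sign, mask, mass)
.observed_clusters <- function(stat, thr, excl) {
  cl <- list()
  for (sgn in c(1, -1)) {
    m <- !excl & !is.na(stat) & sgn * stat > thr
    if (!any(m)) next
    lab <- label_components(m)
    for (k in seq_len(max(lab))) {
      msk <- lab == k
      cl[[length(cl) + 1L]] <- list(sign = sgn, mask = msk,
                                    mass = sum(stat[msk]))
    }
  }
  if (length(cl))
    cl <- cl[order(-abs(vapply(cl, `[[`, numeric(1), "mass")))]
  cl
}

.as_group_array <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    x <- array(unlist(lapply(x, as.numeric)), c(d, length(x)))
    x <- aperm(x, c(3, 1, 2))
  }
  x
}

#' Paired (or one-sample) cluster-based permutation test on 2-D maps
#'
#' Elementwise paired t statistics across participants, clusters formed from
#' 4-connected suprathreshold bins of one sign (two-tailed cluster-forming
#' threshold \code{alpha_cf}), cluster mass = sum of t within the cluster.
#' The null distribution of the maximum absolute cluster mass is obtained by
#' random sign flips of the per-participant condition differences (all
#' \code{2^n} flips when that is fewer than \code{n_perm}); cluster p-values
#' use the (b+1)/(m+1) estimator. Bins with zero variance or missing in any
#' participant are excluded.
#'
#' @param x Participant x dim1 x dim2 array (or list of matrices) for
#'   condition A.
#' @param y Same for condition B; \code{NULL} gives a one-sample test of
#'   \code{x} against 0.
#' @param alpha_cf Two-tailed cluster-forming alpha.
#' @param n_perm Maximum number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @return An object of class \code{ers_clusters}: observed t map, cluster
#'   list (sign, mask, mass, p), threshold, null maxima, n_perm, seed.
#' @export
cluster_permutation_paired <- function(x, y = NULL, alpha_cf = 0.05,
                                       n_perm = 1000, seed = NULL) {
  x <- .as_group_array(x)
  if (!is.null(y)) {
    y <- .as_group_array(y)
    stopifnot(all(dim(x) == dim(y)))
    d <- x - y
  } else d <- x
  n <- dim(d)[1]
  if (n < 2) stop("need at least 2 participants")
  dims <- dim(d)[2:3]
  D <- matrix(d, n)                      # n x bins
  excl <- apply(D, 2, function(v) anyNA(v) || stats::var(v) == 0)
  D[, excl] <- 0
  mobs <- colMeans(D)
  msq <- colMeans(D^2)
  tv <- mobs / sqrt(pmax(msq - mobs^2, 0) / (n - 1))
  tv[excl] <- NA_real_
  thr <- stats::qt(1 - alpha_cf / 2, n - 1)
  stat <- matrix(tv, dims[1], dims[2])
  exclm <- matrix(excl, dims[1], dims[2])
  clusters <- .observed_clusters(stat, thr, exclm)

  if (!is.null(seed)) set.seed(seed)
  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(S)
  } else {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  null_max <- numeric(n_perm)
  chunk <- 200L
  b0 <- 1L
  while (b0 <= n_perm) {
    rows <- b0:min(b0 + chunk - 1L, n_perm)
    M <- (S[rows, , drop = FALSE] %*% D) / n
    Tm <- M / sqrt(pmax(msq[col(M)] - M^2, 0) / (n - 1))
    Tm[, excl] <- NA_real_
    for (r in seq_along(rows)) {
      null_max[rows[r]] <-
        .max_cluster_mass(matrix(Tm[r, ], dims[1], dims[2]), thr, exclm)
    }
    b0 <- b0 + chunk
  }
  for (k in seq_along(clusters))
    clusters[[k]]$p <- (sum(null_max >= abs(clusters[[k]]$mass)) + 1) /
      (n_perm + 1)
  structure(list(stat = stat, df = n - 1, threshold = thr,
                 clusters = clusters, null_max = null_max,
                 n_perm = n_perm, seed = seed, kind = "paired_t"),
            class = "ers_clusters")
}

#' Omnibus one-way repeated-measures ANOVA cluster permutation test
#'
#' Elementwise one-way RM-ANOVA F over k conditions; clusters of
#' suprathreshold F bins (one-tailed \code{alpha_cf}); null distribution by
#' permuting condition labels within participants.
#'
#' @param x Participant x condition x dim1 x dim2 array (or list over
#'   conditions of participant x dim1 x dim2 arrays).
#' @inheritParams cluster_permutation_paired
#' @return An \code{ers_clusters} object (F map, positive clusters only).
#' @export
cluster_permutation_F <- function(x, alpha_cf = 0.05, n_perm = 1000,
                                  seed = NULL) {
  if (is.list(x)) {
    arrs <- lapply(x, .as_group_array)
    d <- dim(arrs[[1]])
    x <- array(NA_real_, c(d[1], length(arrs), d[2], d[3]))
    for (c in seq_along(arrs)) x[, c, , ] <- arrs[[c]]
  }
  n <- dim(x)[1]; k <- dim(x)[2]; dims <- dim(x)[3:4]
  if (k < 3) stop("need k >= 3 conditions")
  B <- prod(dims)
  A <- array(x, c(n, k, B))
  excl <- vapply(seq_len(B), function(b) {
    v <- A[, , b]
    anyNA(v) || stats::var(as.vector(v)) == 0
  }, logical(1))
  A[, , excl] <- 0

  f_map <- function(A) {
    grand <- colMeans(matrix(A, n * k))
    m_sub <- apply(A, c(1, 3), mean)          # n x B
    SS_A <- numeric(B); SS_err <- numeric(B)
    for (c in seq_len(k)) {
      Ac <- matrix(A[, c, ], n)
      mc <- colMeans(Ac)
      SS_A <- SS_A + (mc - grand)^2
      # residual: x - subject mean - condition mean + grand mean
      R <- Ac - m_sub - matrix(mc, n, B, byrow = TRUE) +
        matrix(grand, n, B, byrow = TRUE)
      SS_err <- SS_err + colSums(R^2)
    }
    SS_A <- n * SS_A
    (SS_A / (k - 1)) / (SS_err / ((k - 1) * (n - 1)))
  }
  Fv <- f_map(A)
  Fv[excl] <- NA_real_
  thr <- stats::qf(1 - alpha_cf, k - 1, (k - 1) * (n - 1))
  stat <- matrix(Fv, dims[1], dims[2])
  exclm <- matrix(excl, dims[1], dims[2])
  clusters <- .observed_clusters(stat, thr, exclm)

  if (!is.null(seed)) set.seed(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Ap <- A
    for (i in seq_len(n)) Ap[i, , ] <- A[i, sample(k), ]
    Fp <- f_map(Ap)
    Fp[excl] <- NA_real_
    null_max[p] <- .max_cluster_mass(matrix(Fp, dims[1], dims[2]), thr,
                                     exclm)
  }
  for (j in seq_along(clusters))
    clusters[[j]]$p <- (sum(null_max >= clusters[[j]]$mass) + 1) /
      (n_perm + 1)
  structure(list(stat = stat, df = c(k - 1, (k - 1) * (n - 1)),
                 threshold = thr, clusters = clusters, null_max = null_max,
                 n_perm = n_perm, seed = seed, kind = "rm_anova_F"),
            class = "ers_clusters")
}

#' @export
print.ers_clusters <- function(x, ...) {
  cat("<ers_clusters> ", x$kind, ", ", length(x$clusters),
      " cluster(s), ", x$n_perm, " permutations\n", sep = "")
  show <- utils::head(x$clusters, 5L)
  for (cl in show)
    cat(sprintf("  sign %+d  mass %9.2f  bins %4d  p = %.4f\n", cl$sign,
                cl$mass, sum(cl$mask), cl$p))
  if (length(x$clusters) > length(show))
    cat("  ... ", length(x$clusters) - length(show),
        " smaller cluster(s) not shown\n", sep = "")
  invisible(x)
}

#' Union mask of significant clusters of one sign
#' @param res An \code{ers_clusters} result.
#' @param alpha Significance level for cluster p-values.
#' @param sign +1 or -1.
#' @return Logical matrix.
#' @export
significant_mask <- function(res, alpha = 0.05, sign = 1) {
  m <- matrix(FALSE, nrow(res$stat), ncol(res$stat))
  for (cl in res$clusters)
    if (cl$sign == sign && cl$p < alpha) m <- m | cl$mask
  m
}

#' Minimum-t conjunction of two cluster results
#'
#' Intersection of the unions of significant positive clusters of two
#' contrasts computed on the same grid, displayed as the elementwise minimum
#' of the two t maps inside the intersection.
#'
#' @param resA,resB \code{ers_clusters} results on congruent grids.
#' @param alpha Cluster significance level.
#' @return A list: \code{mask} (logical matrix) and \code{min_t} (numeric
#'   matrix, NA outside the mask).
#' @export
conjunction_min_t <- function(resA, resB, alpha = 0.05) {
  if (!all(dim(resA$stat) == dim(resB$stat))) stop("grids mismatch")
  mask <- significant_mask(resA, alpha, 1) & significant_mask(resB, alpha, 1)
  mt <- matrix(NA_real_, nrow(mask), ncol(mask))
  mt[mask] <- pmin(resA$stat, resB$stat)[mask]
  list(mask = mask, min_t = mt)
}
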