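#' Plot a reinstatement map
#'
#' Image of an encoding-time x retrieval-time correlation map with the
#' diagonal marked; optionally overlays the outline of a significance mask
#' (e.g. a conjunction mask).
#'
#' @param x An \code{ers_map}.
#' @param mask Optional logical matrix (same grid) outlined on top.
#' @param zlim Colour range; defaults to a symmetric range around 0.
#' @param main Title.
#' @param ... Passed to \code{image}.
#' @return Invisibly, \code{x}.
#' @export
plot.ers_map <- function(x, mask = NULL, zlim = NULL, main = NULL, ...) {
  et <- attr(x, "enc_times"); rt <- attr(x, "ret_times")
  z <- unclass(x)
  if (is.null(zlim)) {
    m <- max(abs(z), na.rm = TRUE)
    zlim <- c(-m, m)
  }
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(et, rt, z, zlim = zlim, col = pal,
                  xlab = "encoding time (s)",
                  ylab = paste0("retrieval time (s, ", attr(x, "lock"),
                                "-locked)"),
                  main = main %||% paste0("reinstatement (",
                                          attr(x, "provenance"), ", ",
                                          attr(x, "scale"), ")"), ...)
  if (attr(x, "lock") == "stimulus")
    graphics::abline(0, 1, lty = 2, col = "grey30")
  if (!is.null(mask) && any(mask))
    graphics::contour(et, rt, mask + 0, levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  invisible(x)
}

#' Plot a cluster-test statistic map
#'
#' Image of the observed t (or F) map with significant clusters outlined.
#'
#' @param x An \code{ers_clusters} result.
#' @param xcoord,ycoord Coordinates of the map rows/columns (e.g.
#'   frequencies and times); defaults to bin indices.
#' @param alpha Significance level for outlining clusters.
#' @param xlab,ylab,main Axis labels and title.
#' @param ... Passed to \code{image}.
#' @return Invisibly, \code{x}.
#' @export
plot.ers_clusters <- function(x, xcoord = NULL, ycoord = NULL, alpha = 0.05,
                              xlab = "", ylab = "", main = NULL, ...) {
  z <- x$stat
  if (is.null(xcoord)) xcoord <- seq_len(nrow(z))
  if (is.null(ycoord)) ycoord <- seq_len(ncol(z))
  m <- max(abs(z), na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(xcoord, ycoord, z, zlim = c(-m, m), col = pal,
                  xlab = xlab, ylab = ylab,
                  main = main %||% paste0(x$kind, " map"), ...)
  sig <- significant_mask(x, alpha, 1) | significant_mask(x, alpha, -1)
  if (any(sig))
    graphics::contour(xcoord, ycoord, sig + 0, levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  invisible(x)
}

#' Tabulate clusters of a permutation test
#'
#' One row per cluster with its sign, mass, bin count, permutation p-value
#' and, when coordinates are supplied, the bounding box of the cluster on
#' the map's axes (e.g. Hz x s for time-frequency maps, s x s for
#' reinstatement maps). This is the serializable summary the pipeline
#' report carries.
#'
#' @param res An \code{ers_clusters} result.
#' @param xcoord,ycoord Optional coordinates of the map rows/columns.
#' @return A data frame, ordered by decreasing |mass|.
#' @export
cluster_table <- function(res, xcoord = NULL, ycoord = NULL) {
  if (!length(res$clusters))
    return(data.frame(sign = integer(0), mass = numeric(0),
                      n_bins = integer(0), p = numeric(0)))
  rows <- lapply(res$clusters, function(cl) {
    out <- data.frame(sign = cl$sign, mass = cl$mass,
                      n_bins = sum(cl$mask), p = cl$p)
    if (!is.null(xcoord)) {
      i <- range(which(rowSums(cl$mask) > 0))
      out$x_lo <- xcoord[i[1]]; out$x_hi <- xcoord[i[2]]
    }
    if (!is.null(ycoord)) {
      j <- range(which(colSums(cl$mask) > 0))
      out$y_lo <- ycoord[j[1]]; out$y_hi <- ycoord[j[2]]
    }
    out
  })
  do.call(rbind, rows)
}
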