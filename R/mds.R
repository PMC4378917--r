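#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and keeps the leading
#' `dims` non-negative eigenvalues; coordinates are eigenvectors scaled
#' by the square root of their eigenvalue.  A `1 - proximity`
#' dissimilarity is generally non-Euclidean, so negative eigenvalues are
#' truncated to zero and their relative mass reported as a quality
#' diagnostic.  Eigenvector signs are fixed by making the
#' largest-magnitude entry of each column positive, so coordinates are
#' reproducible across runs and platforms (up to that convention the
#' embedding is only defined up to orthogonal rotation).
#'
#' @param D symmetric zero-diagonal dissimilarity matrix.
#' @param dims number of embedding dimensions, `1 <= dims < n`.
#' @return An `rf_embedding` list: `coordinates` (n x dims, column means
#'   zero, columns ordered by decreasing eigenvalue), `eigenvalues`
#'   (leading `dims`, truncated at zero) and `negative_eigenvalue_mass`
#'   (sum of |negative eigenvalues| / sum of |eigenvalues|).
#' @export
classical_mds <- function(D, dims = 2) {
  check_dissimilarity(D)
  n <- nrow(D)
  if (dims < 1 || dims >= n) stop("dims must be in [1, n - 1]")
  fit <- suppressWarnings(cmdscale(stats::as.dist(D), k = dims, eig = TRUE))
  eig <- fit$eig
  pts <- fit$points
  if (ncol(pts) < dims)  # non-positive eigenvalues truncated: pad zeros
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  for (j in seq_len(dims)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("mds", seq_len(dims))
  neg_mass <- if (any(eig < 0)) sum(abs(eig[eig < 0])) / sum(abs(eig)) else 0
  structure(list(coordinates = pts,
                 eigenvalues = pmax(eig[seq_len(dims)], 0),
                 negative_eigenvalue_mass = neg_mass),
            class = "rf_embedding")
}

#' @export
print.rf_embedding <- function(x, ...) {
  cat("classical MDS embedding:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "dims; eigenvalues",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      sprintf("; negative-eigenvalue mass %.3f\n",
              x$negative_eigenvalue_mass))
  invisible(x)
}

#' Scatter plot of an embedding colored by class
#'
#' @param x an `rf_embedding`.
#' @param classes optional factor of class labels per point.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rf_embedding <- function(x, classes = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) co <- cbind(co, 0)
  if (is.null(classes)) {
    graphics::plot(co[, 1], co[, 2], xlab = "MDS 1", ylab = "MDS 2", ...)
  } else {
    classes <- as.factor(classes)
    pal <- grDevices::hcl.colors(max(3, nlevels(classes)), "Dark 3")
    graphics::plot(co[, 1], co[, 2], col = pal[as.integer(classes)],
                   pch = 19, xlab = "MDS 1", ylab = "MDS 2", ...)
    graphics::legend("topright", legend = levels(classes),
                     col = pal[seq_len(nlevels(classes))], pch = 19,
                     bty = "n")
  }
  invisible(x)
}
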