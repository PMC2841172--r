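#' Principal component ordination of shape variables
#'
#' Centered PCA through the spectral decomposition of the covariance
#' matrix of the shape variables.  Because the shape-variable basis is
#' orthonormal on tangent coordinates, the full set of PC scores is a
#' rigid rotation of shape space: pairwise score distances equal shape
#' distances.  Each PC's sign is fixed so the largest-magnitude loading is
#' positive.
#'
#' @param x an n x p shape matrix (n > 2).
#' @return object of class `shape_pca`: `scores`, `loadings`, `sdev`,
#'   `explained` (variance fractions), `center`.
#' @export
shape_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) <= 2L) stop("PCA needs n > 2", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  e <- eigen(stats::cov(xc), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rot <- e$vectors
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xc %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  structure(list(scores = scores, loadings = rot, sdev = sqrt(vals),
                 explained = vals / sum(vals), center = ctr),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,", ncol(x$scores), "axes\n")
  cat("  PC1-PC2 explain",
      sprintf("%.1f%%", 100 * sum(x$explained[1:2])), "of total variation\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, ...) {
  plot(x$scores[, 1], x$scores[, 2],
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]),
       pch = 16, col = "grey60", asp = 1, ...)
  invisible(x)
}
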