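#' Center a configuration and scale it to unit centroid size
#'
#' @param x a k x 2 coordinate matrix.
#' @param tol degeneracy tolerance on centroid size.
#' @return the centered configuration with centroid size 1.
#' @export
center_scale <- function(x, tol = 1e-12) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  cs <- sqrt(sum(xc^2))
  if (!is.finite(cs) || cs < tol)
    stop("degenerate configuration: all landmarks coincident", call. = FALSE)
  xc / cs
}

# optimal 2-D rotation (det +1, no reflection) of centered y onto centered x.
# For M = t(y) %*% x the optimum over rotations [[c,-s],[s,c]] maximizes
# c*(M11+M22) + s*(M21-M12), giving the closed form below (equivalent to the
# SVD solution with the determinant constraint).
rot2_onto <- function(y, x) {
  m <- crossprod(y, x)
  a <- m[1, 1] + m[2, 2]
  b <- m[2, 1] - m[1, 2]
  h <- sqrt(a * a + b * b)
  if (h < 1e-300) return(diag(2))
  matrix(c(a, b, -b, a) / h, 2, 2)
}

# deterministic orientation: rotate so the consensus' major principal axis
# lies along x, with the sign fixed by the landmark of largest |x|.  Makes
# downstream shape variables invariant to a common rotation of the data.
canonical_rotation <- function(cons) {
  e <- eigen(crossprod(cons), symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  P <- cons %*% R
  j <- which.max(abs(P[, 1]))
  if (P[j, 1] < 0) R <- -R
  R
}

#' Generalized Procrustes superimposition
#'
#' Removes position, scale and rotation: every configuration is centered
#' and scaled to unit centroid size, then iteratively rotated (rotation
#' only, determinant +1 -- reflections are disallowed because landmark data
#' have a fixed anatomical orientation) onto the running consensus, which
#' is updated as the arithmetic mean and re-normalized to unit size.
#' Iteration stops when the change in the total squared distance to the
#' consensus falls below `tol`.  The converged solution is rotated to a
#' canonical orientation (consensus major axis along x) so results do not
#' depend on the arbitrary orientation of the input.
#'
#' @param x a `landmark_dataset`, k x 2 x n array, or list of k x 2 matrices.
#' @param tol convergence tolerance on the change in total residual sum of
#'   squares (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return an object of class `gpa`: `aligned` (k x 2 x n), `consensus`
#'   (arithmetic mean of the aligned specimens), `consensus_unit` (the
#'   unit-size consensus used for tangent-space projection),
#'   `centroid_sizes`, `rss`, `rss_path`, `iterations`, `ids`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  a <- as_config_array(x)
  ids <- config_ids(a)
  k <- dim(a)[1]
  n <- dim(a)[3]
  if (n < 2L) stop("GPA needs at least 2 specimens", call. = FALSE)
  if (k < 3L) stop("GPA needs at least 3 landmarks", call. = FALSE)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    sizes[i] <- centroid_size(a[, , i])
    a[, , i] <- center_scale(a[, , i])
  }
  cons <- a[, , 1]
  q_old <- Inf
  q_path <- numeric(0)
  converged <- FALSE
  change <- NA_real_
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) a[, , i] <- a[, , i] %*% rot2_onto(a[, , i], cons)
    m <- rowMeans(a, dims = 2)
    cons <- m / sqrt(sum(m^2))
    # each aligned specimen and the consensus have unit norm
    q <- 2 * n - 2 * sum(as.vector(a) * rep(as.vector(cons), n))
    q_path <- c(q_path, q)
    change <- abs(q_old - q)
    if (change < tol) { converged <- TRUE; break }
    q_old <- q
  }
  if (!converged)
    stop("GPA did not converge in ", max_iter,
         " iterations; last change in residual SS = ",
         format(change, digits = 4), call. = FALSE)
  R <- canonical_rotation(cons)
  cons <- cons %*% R
  for (i in seq_len(n)) a[, , i] <- a[, , i] %*% R
  dimnames(a) <- list(NULL, c("x", "y"), ids)
  structure(list(aligned = a,
                 consensus = rowMeans(a, dims = 2),
                 consensus_unit = cons,
                 centroid_sizes = stats::setNames(sizes, ids),
                 rss = q_path[length(q_path)],
                 rss_path = q_path,
                 iterations = length(q_path),
                 ids = ids),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes superimposition\n")
  cat("  specimens:", dim(x$aligned)[3], " landmarks:", dim(x$aligned)[1], "\n")
  cat("  iterations:", x$iterations,
      " residual SS:", format(x$rss, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.gpa <- function(x, ...) {
  a <- x$aligned
  plot(a[, 1, ], a[, 2, ], pch = 16, cex = 0.3, col = "grey70", asp = 1,
       xlab = "x", ylab = "y", main = "Procrustes-aligned landmarks", ...)
  points(x$consensus, pch = 21, bg = "red", cex = 1.2)
  invisible(x)
}

#' Procrustes distance between two shapes
#'
#' Root summed squared landmark differences after both configurations are
#' centered, scaled to unit centroid size, and the second is optimally
#' rotated (no reflection) onto the first; zero iff the shapes coincide.
#'
#' @param a,b k x 2 coordinate matrices with identical landmark counts.
#' @return a nonnegative scalar (partial Procrustes distance).
#' @export
procrustes_distance <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mismatched landmark configurations", call. = FALSE)
  a <- center_scale(a)
  b <- center_scale(b)
  b <- b %*% rot2_onto(b, a)
  sqrt(sum((a - b)^2))
}
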