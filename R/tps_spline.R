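# thin-plate spline machinery: bending energy, interpolation, grids

tps_kernel <- function(r2) {
  u <- r2
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos])
  u[!pos] <- 0
  u
}

tps_L <- function(ref, tol = 1e-12) {
  k <- nrow(ref)
  d2 <- as.matrix(dist(ref))^2
  if (any(d2[upper.tri(d2)] < tol))
    stop("singular thin-plate-spline kernel: coincident landmarks",
         call. = FALSE)
  K <- tps_kernel(d2)
  Q <- cbind(1, ref)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
}

#' Thin-plate-spline bending energy matrix
#'
#' Builds the k x k bending energy matrix of a reference configuration from
#' the radial kernel r^2 log r^2 with the affine terms projected out: the
#' upper-left k x k block of the inverse of the bordered kernel matrix.
#' The result is symmetric, positive semidefinite, and has rank k - 3 (its
#' null space is spanned by the constant vector and the x and y
#' coordinates, i.e. affine deformations cost no bending).
#'
#' @param ref a k x 2 reference (consensus) configuration with pairwise
#'   distinct landmarks.
#' @return a symmetric k x k matrix.
#' @export
bending_energy <- function(ref) {
  k <- nrow(ref)
  L <- tps_L(ref)
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular thin-plate-spline system", call. = FALSE))
  Be <- Li[1:k, 1:k]
  unname((Be + t(Be)) / 2)
}

# interpolant mapping ref -> target; returns function(points) -> warped points
# plus the bending energy of the map as an attribute
tps_interpolator <- function(ref, target) {
  k <- nrow(ref)
  L <- tps_L(ref)
  rhs <- rbind(target, matrix(0, 3, 2))
  W <- solve(L, rhs)
  Wk <- W[1:k, , drop = FALSE]
  A <- W[(k + 1):(k + 3), , drop = FALSE]
  K <- tps_kernel(as.matrix(dist(ref))^2)
  be <- sum(diag(t(Wk) %*% K %*% Wk))
  f <- function(pts) {
    pts <- as.matrix(pts)
    d2 <- outer(pts[, 1], ref[, 1], "-")^2 + outer(pts[, 2], ref[, 2], "-")^2
    U <- tps_kernel(d2)
    cbind(1, pts) %*% A + U %*% Wk
  }
  attr(f, "bending_energy") <- be
  f
}

#' Thin-plate-spline deformation grid
#'
#' Computes the TPS interpolant mapping a reference configuration onto a
#' target (the interpolant passes exactly through every landmark) and
#' applies it to a rectangular grid bounding the reference.
#'
#' @param reference k x 2 reference configuration (pairwise distinct points).
#' @param target k x 2 target configuration.
#' @param resolution number of grid cells per axis (default 24).
#' @param margin fractional margin added around the reference bounding box
#'   (default 0.1).
#' @return an object of class `tps_grid`: `grid` (original grid points),
#'   `warped` (their images), `nx`, `ny`, `reference`, `target`, and
#'   `bending_energy` of the deformation (zero iff the map is affine).
#' @export
tps_grid <- function(reference, target, resolution = 24L, margin = 0.1) {
  f <- tps_interpolator(reference, target)
  rx <- range(reference[, 1]); ry <- range(reference[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = resolution + 1L)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = resolution + 1L)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  structure(list(grid = grid, warped = f(grid),
                 nx = length(gx), ny = length(gy),
                 reference = reference, target = target,
                 bending_energy = attr(f, "bending_energy")),
            class = "tps_grid")
}

#' @export
plot.tps_grid <- function(x, main = "", ...) {
  w <- x$warped
  plot(range(w[, 1]), range(w[, 2]), type = "n", asp = 1, xlab = "", ylab = "",
       axes = FALSE, main = main, ...)
  nx <- x$nx; ny <- x$ny
  for (j in seq_len(ny))
    lines(w[((j - 1) * nx + 1):(j * nx), ], col = "grey60")
  for (i in seq_len(nx))
    lines(w[seq(i, nx * ny, by = nx), ], col = "grey60")
  points(x$target, pch = 16, cex = 0.8)
  invisible(x)
}
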