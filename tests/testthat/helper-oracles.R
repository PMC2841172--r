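# independent oracles kept deliberately separate from the package internals

# closed-form ordinary Procrustes alignment of b onto a (rotation only,
# determinant +1) via the SVD of the cross-product matrix
opa_svd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  s <- svd(crossprod(b, a))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  br <- b %*% R
  list(aligned = br, distance = sqrt(sum((a - br)^2)), rotation = R)
}

# tangent-space Procrustes distance between two aligned specimens of a gpa
# fit, computed by explicit projection (removes translations, the consensus
# scale direction, and the consensus rotation direction)
tangent_dist_oracle <- function(g, i, j) {
  cons <- g$consensus_unit
  k <- nrow(cons)
  v <- as.vector(g$aligned[, , i] - g$aligned[, , j])
  basis <- cbind(c(rep(1, k), rep(0, k)) / sqrt(k),
                 c(rep(0, k), rep(1, k)) / sqrt(k),
                 as.vector(cons),
                 as.vector(cbind(-cons[, 2], cons[, 1])))
  for (c_ in seq_len(ncol(basis)))
    v <- v - basis[, c_] * sum(v * basis[, c_])
  sqrt(sum(v^2))
}

# independent full-enumeration RRPP p-value for a univariate two-group
# |mean difference| statistic with an intercept-only reduced model
enum_rrpp_pvalue <- function(y, g) {
  n <- length(y)
  fit0 <- rep(mean(y), n)
  res <- y - fit0
  stat <- function(yy) abs(mean(yy[g == levels(g)[1]]) -
                             mean(yy[g == levels(g)[2]]))
  obs <- stat(y)
  perm_rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_rec(v[-i]), function(p) c(v[i], p)))
    out
  }
  vals <- vapply(perm_rec(seq_len(n)),
                 function(idx) stat(fit0 + res[idx]), numeric(1))
  mean(vals >= obs - 1e-12)
}

# textbook bending-energy construction with explicit loops (independent of
# the vectorized package code)
bending_energy_textbook <- function(ref) {
  k <- nrow(ref)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    r2 <- sum((ref[i, ] - ref[j, ])^2)
    K[i, j] <- r2 * log(r2)
  }
  Q <- cbind(rep(1, k), ref[, 1], ref[, 2])
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

rand_rotation <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * p), p)))
}
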