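# tangent-space shape variables: partial warps + standard uniform components

#' Orthonormal tangent-space basis at a consensus configuration
#'
#' Constructs the 2k x (2k - 4) orthonormal basis of the shape tangent
#' space at a unit-size consensus: 2(k - 3) partial-warp directions (the
#' non-affine eigenvectors of the bending-energy matrix applied to the x
#' and y coordinate directions) plus 2 standard uniform components spanning
#' the affine complement.  Vectors are laid out as c(x_1..x_k, y_1..y_k).
#'
#' The uniform pair is fixed by convention: the first is the (projected)
#' x-shear field (y, 0), the second the orthonormal remainder oriented
#' along the projected y-dilation field (0, y).  Any orthonormal rotation
#' within the basis leaves all downstream vector statistics unchanged.
#'
#' @param cons a k x 2 consensus with unit centroid size, centered at the
#'   origin.
#' @return a 2k x (2k - 4) matrix with a `meta` attribute (data frame with
#'   columns `component`, `index`, `axis`).
#' @export
tangent_basis <- function(cons) {
  k <- nrow(cons)
  Be <- bending_energy(cons)
  e <- eigen(Be, symmetric = TRUE)
  nz <- e$values > max(e$values) * 1e-9
  if (sum(nz) != k - 3L)
    stop("bending-energy matrix does not have rank k - 3", call. = FALSE)
  # order partial warps from largest-scale (smallest bending energy) up;
  # eigenvector signs are arbitrary, so fix each by its largest component
  E <- e$vectors[, which(nz)[order(e$values[nz])], drop = FALSE]
  for (j in seq_len(ncol(E))) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  zero <- rep(0, k)
  npw <- k - 3L
  pw <- matrix(0, 2 * k, 2 * npw)
  for (j in seq_len(npw)) {
    pw[, 2 * j - 1] <- c(E[, j], zero)
    pw[, 2 * j] <- c(zero, E[, j])
  }
  # uniform components: affine fields orthogonal to translation/scale/rotation
  xs <- cons[, 1]; ys <- cons[, 2]
  one <- rep(1, k)
  S <- cbind(c(one, zero), c(zero, one), c(xs, ys), c(-ys, xs))
  cand <- cbind(c(ys, zero), c(zero, ys))  # x-shear, y-dilation fields
  Pc <- cand - S %*% solve(crossprod(S), crossprod(S, cand))
  u1 <- Pc[, 1] / sqrt(sum(Pc[, 1]^2))
  u2 <- Pc[, 2] - u1 * sum(u1 * Pc[, 2])
  u2 <- u2 / sqrt(sum(u2^2))
  B <- cbind(u1, u2, pw)
  colnames(B) <- c("U1", "U2",
                   paste0("PW", rep(seq_len(npw), each = 2), c("x", "y")))
  attr(B, "meta") <- data.frame(
    component = c("uniform", "uniform", rep("pw", 2 * npw)),
    index = c(1L, 2L, rep(seq_len(npw), each = 2)),
    axis = c("U1", "U2", rep(c("x", "y"), npw)),
    stringsAsFactors = FALSE)
  B
}

new_shape_matrix <- function(values, meta, bases) {
  structure(values, meta = meta, bases = bases,
            class = c("shape_matrix", class(values)))
}

#' Tangent-space shape variables from a Procrustes superimposition
#'
#' Projects the Procrustes residuals (aligned specimen minus unit
#' consensus) onto the orthonormal partial-warp plus uniform-component
#' basis.  Because the basis is orthonormal on tangent coordinates,
#' Euclidean distances among rows equal tangent-space Procrustes distances
#' among the aligned shapes, so downstream statistics do not depend on the
#' particular basis.
#'
#' @param aligned a `gpa` object.
#' @param subset subset label recorded in the column metadata.
#' @return an n x (2k - 4) `shape_matrix` with specimen ids as row names
#'   and attributes `meta` (column provenance) and `bases` (per-subset
#'   consensus and basis, used to map scores back to landmark space).
#' @export
shape_variables <- function(aligned, subset = "all") {
  if (!inherits(aligned, "gpa")) aligned <- gpa(aligned)
  cons <- aligned$consensus_unit
  k <- nrow(cons)
  n <- dim(aligned$aligned)[3]
  B <- tangent_basis(cons)
  res <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) res[i, ] <- as.vector(aligned$aligned[, , i] - cons)
  scores <- res %*% B
  rownames(scores) <- aligned$ids
  colnames(scores) <- paste(subset, colnames(B), sep = ".")
  meta <- cbind(subset = subset, attr(B, "meta"), stringsAsFactors = FALSE)
  bases <- stats::setNames(list(list(consensus = cons, basis = B, gpa = aligned)),
                           subset)
  new_shape_matrix(scores, meta, bases)
}

#' Separate-subset shape variables for articulated structures
#'
#' Runs an independent Procrustes superimposition and tangent projection
#' within each partition group (e.g. skull and jaw) and concatenates the
#' resulting shape variables, so articulation (gape) variation between the
#' structures is excluded from shape.  Each group of k_g landmarks
#' contributes 2 k_g - 4 columns.
#'
#' @param x a `landmark_dataset`, k x 2 x n array, or list of k x 2
#'   matrices.
#' @param partition a [landmark_partition()]; defaults to the partition
#'   stored in a `landmark_dataset`, or a single all-landmark group.
#' @return an n x p `shape_matrix`, p = sum over groups of (2 k_g - 4).
#' @export
separate_subset_shape <- function(x, partition = NULL) {
  if (inherits(x, "landmark_dataset")) partition <- partition %||% x$partition
  a <- as_config_array(x)
  if (is.null(partition)) return(shape_variables(gpa(a)))
  if (!inherits(partition, "landmark_partition"))
    partition <- landmark_partition(partition)
  pieces <- lapply(names(partition), function(nm) {
    idx <- partition[[nm]]
    if (any(idx > dim(a)[1]))
      stop("partition group '", nm, "' indexes beyond k = ", dim(a)[1],
           call. = FALSE)
    shape_variables(gpa(a[idx, , , drop = FALSE]), subset = nm)
  })
  values <- do.call(cbind, lapply(pieces, unclass))
  meta <- do.call(rbind, lapply(pieces, attr, "meta"))
  bases <- do.call(c, lapply(pieces, attr, "bases"))
  new_shape_matrix(values, meta, bases)
}

#' Map shape-variable scores back to landmark configurations
#'
#' Inverts the tangent projection for one row of scores: for each subset,
#' consensus + basis %*% scores.  Used for deformation grids of fitted
#' cell means.
#'
#' @param sm a `shape_matrix` (provides the per-subset consensus and basis).
#' @param scores a numeric vector of length ncol(sm) (e.g. one LS mean row).
#' @return a named list of k_g x 2 configurations, one per subset.
#' @export
shape_from_scores <- function(sm, scores) {
  bases <- attr(sm, "bases")
  meta <- attr(sm, "meta")
  out <- list()
  for (nm in names(bases)) {
    sel <- meta$subset == nm
    b <- bases[[nm]]
    out[[nm]] <- b$consensus +
      unvec_config(b$basis %*% scores[sel], nrow(b$consensus))
  }
  out
}

#' Write a shape matrix as CSV (column metadata encoded in the header)
#' @param sm a `shape_matrix`.
#' @param path output path.
#' @export
write_shape_csv <- function(sm, path) {
  df <- data.frame(specimen_id = rownames(sm), unclass(sm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
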