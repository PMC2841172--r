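# internal helpers shared across modules

# k x 2 configuration <-> length-2k vector, layout c(x_1..x_k, y_1..y_k)
vec_config <- function(x) as.vector(x)
unvec_config <- function(v, k) matrix(v, nrow = k, ncol = 2)

centroid_size <- function(x) {
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce landmark input (landmark_dataset, k x 2 x n array, or list of k x 2
# matrices) to a k x 2 x n array with specimen ids in dimnames
as_config_array <- function(x) {
  if (inherits(x, "landmark_dataset")) return(x$coords)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != 2L) stop("configurations must be k x 2 x n", call. = FALSE)
    return(x)
  }
  if (is.list(x)) {
    k <- nrow(x[[1]])
    a <- array(NA_real_, dim = c(k, 2L, length(x)))
    for (i in seq_along(x)) {
      if (!identical(dim(x[[i]]), c(k, 2L)))
        stop("all configurations must share the same landmark count", call. = FALSE)
      a[, , i] <- x[[i]]
    }
    dimnames(a) <- list(NULL, c("x", "y"), names(x))
    return(a)
  }
  if (is.matrix(x) && ncol(x) == 2L) return(array(x, dim = c(nrow(x), 2L, 1L)))
  stop("cannot interpret input as landmark configurations", call. = FALSE)
}

config_ids <- function(a) {
  ids <- dimnames(a)[[3]]
  if (is.null(ids)) ids <- as.character(seq_len(dim(a)[3]))
  ids
}

# angle between two vectors in degrees.  The 2*atan2(|u-v|, |u+v|) form on
# the normalized vectors is accurate near 0 and 180 degrees, where the
# arccosine of the (clamped) dot-product ratio loses half the significant
# digits; both agree exactly in exact arithmetic.
angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  un <- u / nu; vn <- v / nv
  2 * atan2(sqrt(sum((un - vn)^2)), sqrt(sum((un + vn)^2))) * 180 / pi
}
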