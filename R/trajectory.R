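# allopatry -> sympatry evolutionary vectors and their RRPP assessment

#' Allopatry-to-sympatry evolutionary vectors
#'
#' One multivariate vector per species x transect: the sympatric minus the
#' allopatric least-squares mean, with its magnitude (Euclidean norm in
#' Procrustes units).
#'
#' @param lsm an [ls_means()] result over the species x locality x
#'   transect grid.
#' @return an object of class `evolution_vectors`: `delta` (vectors x p
#'   matrix), `species`, `transect`, `magnitude`.
#' @export
evolution_vectors <- function(lsm) {
  cells <- attr(lsm, "cells")
  if (is.null(cells)) stop("lsm must carry a 'cells' attribute", call. = FALSE)
  sp <- levels(droplevels(factor(cells$species)))
  tr <- levels(droplevels(factor(cells$transect)))
  combos <- expand.grid(species = sp, transect = tr,
                        stringsAsFactors = FALSE)
  D <- matrix(0, nrow(combos), nrow(cells))
  for (i in seq_len(nrow(combos))) {
    sel_s <- cells$species == combos$species[i] &
      cells$transect == combos$transect[i] & cells$locality == "sympatric"
    sel_a <- cells$species == combos$species[i] &
      cells$transect == combos$transect[i] & cells$locality == "allopatric"
    if (sum(sel_s) != 1L || sum(sel_a) != 1L)
      stop("LS means missing for species ", combos$species[i], ", transect ",
           combos$transect[i], call. = FALSE)
    D[i, sel_s] <- 1; D[i, sel_a] <- -1
  }
  delta <- D %*% unclass(lsm)
  rownames(delta) <- paste(combos$species, combos$transect, sep = ".")
  structure(list(delta = delta, species = combos$species,
                 transect = combos$transect,
                 magnitude = sqrt(rowSums(delta^2)),
                 D = D),
            class = "evolution_vectors")
}

#' @export
print.evolution_vectors <- function(x, digits = 5, ...) {
  cat("Evolutionary vectors (sympatric - allopatric LS means)\n")
  print(data.frame(species = x$species, transect = x$transect,
                   magnitude = round(x$magnitude, digits)), row.names = FALSE)
  invisible(x)
}

#' Pairwise magnitude differences and orientations of evolution vectors
#'
#' For each within-species pair of transects, the absolute magnitude
#' difference MD = |d_i - d_j| and the orientation angle theta (degrees)
#' between the two vectors.  The angle is evaluated in a form that is
#' numerically exact at 0 and 180 degrees (see `angle_deg` in the source),
#' equivalent to the arccosine of the clamped dot-product ratio.
#'
#' @param vectors an `evolution_vectors` object.
#' @return data frame with columns species, pair, MD, theta.
#' @export
pairwise_vector_stats <- function(vectors) {
  if (any(vectors$magnitude == 0)) {
    z <- paste(vectors$species, vectors$transect,
               sep = ".")[vectors$magnitude == 0]
    stop("zero-magnitude vector(s): ", paste(z, collapse = ", "),
         "; orientation is undefined", call. = FALSE)
  }
  out <- list()
  for (sp in unique(vectors$species)) {
    idx <- which(vectors$species == sp)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      out[[length(out) + 1L]] <- data.frame(
        species = sp,
        pair = paste(vectors$transect[i], vectors$transect[j], sep = "-"),
        MD = abs(vectors$magnitude[i] - vectors$magnitude[j]),
        theta = angle_deg(vectors$delta[i, ], vectors$delta[j, ]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Angle between the species' mean evolution vectors
#'
#' Averages each species' per-transect vectors and returns the angle in
#' degrees between the two species means.
#'
#' @param vectors an `evolution_vectors` object.
#' @return a scalar angle in degrees.
#' @export
between_species_angle <- function(vectors) {
  sp <- unique(vectors$species)
  if (length(sp) != 2L) stop("need exactly 2 species", call. = FALSE)
  m1 <- colMeans(vectors$delta[vectors$species == sp[1], , drop = FALSE])
  m2 <- colMeans(vectors$delta[vectors$species == sp[2], , drop = FALSE])
  if (all(m1 == 0) || all(m2 == 0))
    stop("zero species mean vector; angle undefined", call. = FALSE)
  angle_deg(m1, m2)
}

#' Summary variance statistics of evolution-vector heterogeneity
#'
#' `Var_size` summarizes heterogeneity of the within-species vector
#' magnitudes, `Var_orient` of the within-species pairwise orientations
#' (degrees squared); both are zero when the vectors are identical within
#' species (perfect parallelism).  Two published readings of each are
#' available:
#' \describe{
#'   \item{size `"pooled_magnitude"` (default)}{pooled variance of the
#'     magnitudes about their species means, denominator N - S.}
#'   \item{size `"pairwise_md"`}{sample variance (n - 1) of the pooled set
#'     of within-species pairwise magnitude differences.}
#'   \item{orient `"pooled_angles"` (default)}{sample variance (n - 1) of
#'     the pooled set of within-species pairwise angles about their pooled
#'     mean.}
#'   \item{orient `"within_species"`}{pooled variance of the pairwise
#'     angles about their species means, denominator N - S.}
#' }
#'
#' @param vectors an `evolution_vectors` object.
#' @param size_method,orient_method see Details.
#' @return named numeric vector `c(Var_size, Var_orient)`.
#' @export
variance_summaries <- function(vectors,
                               size_method = c("pooled_magnitude", "pairwise_md"),
                               orient_method = c("pooled_angles", "within_species")) {
  size_method <- match.arg(size_method)
  orient_method <- match.arg(orient_method)
  pw <- pairwise_vector_stats(vectors)
  sp_of <- factor(vectors$species)
  if (size_method == "pooled_magnitude") {
    dev <- vectors$magnitude - ave(vectors$magnitude, sp_of)
    var_size <- sum(dev^2) / (length(dev) - nlevels(sp_of))
  } else {
    var_size <- stats::var(pw$MD)
  }
  if (orient_method == "pooled_angles") {
    var_orient <- stats::var(pw$theta)
  } else {
    spf <- factor(pw$species)
    dev <- pw$theta - ave(pw$theta, spf)
    var_orient <- sum(dev^2) / (length(dev) - nlevels(spf))
  }
  c(Var_size = var_size, Var_orient = var_orient)
}

# p-value by the (1 + #{null >= observed}) / (nperm + 1) counting rule; the
# observed arrangement plays the role of the identity permutation.  NA null
# values (degenerate statistics) are counted conservatively in the tail.
pval_count <- function(obs, null) {
  tol <- 1e-12 * (1 + abs(obs))
  (1 + sum(is.na(null) | null >= obs - tol)) / (length(null) + 1)
}

all_permutations <- function(n) {
  if (n > 8L) stop("refusing to enumerate more than 8! permutations",
                   call. = FALSE)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Residual randomization permutation procedure (RRPP)
#'
#' Fits the reduced model, then for each permutation adds uniformly
#' permuted whole residual rows back to the reduced-model fitted values
#' and evaluates the requested statistics on the randomized responses
#' (refitting the full model inside `stat_fn`).  P-values follow the
#' (1 + #\{null >= observed\}) / (nperm + 1) rule, so the observed
#' arrangement is included and p > 0 always.  Statistics that are
#' undefined in a permutation (e.g. an angle with a zero-length vector)
#' return NA and are counted conservatively in the null tail; their count
#' is reported.
#'
#' @param Y n x p response matrix.
#' @param factors data frame of specimen factors.
#' @param full,reduced model formulas; `reduced` must nest within `full`.
#' @param stat_fn function taking a randomized n x p response matrix and
#'   returning a named numeric vector of statistics (it should embody the
#'   full-model refit).
#' @param nperm number of random permutations (ignored when
#'   `exact = TRUE`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all n! permutations (n <= 8) instead of Monte
#'   Carlo sampling; p-values are then exact proportions.
#' @return an object of class `rrpp`: `observed`, `pvalues`, `null`
#'   (permutations x statistics matrix), `nperm`, `seed`, `n_degenerate`.
#' @export
rrpp <- function(Y, factors, full, reduced, stat_fn, nperm = 999L,
                 seed = NULL, exact = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  red <- shape_model(Y, factors, reduced)
  F0 <- red$fitted
  R0 <- red$residuals
  obs <- stat_fn(Y)
  if (exact) {
    P <- all_permutations(n)
    null <- matrix(NA_real_, nrow(P), length(obs),
                   dimnames = list(NULL, names(obs)))
    for (b in seq_len(nrow(P)))
      null[b, ] <- stat_fn(F0 + R0[P[b, ], , drop = FALSE])
    pv <- vapply(seq_along(obs), function(j) {
      tol <- 1e-12 * (1 + abs(obs[j]))
      mean(is.na(null[, j]) | null[, j] >= obs[j] - tol)
    }, numeric(1))
    names(pv) <- names(obs)
    return(structure(list(observed = obs, pvalues = pv, null = null,
                          nperm = nrow(P), seed = NULL, exact = TRUE,
                          n_degenerate = colSums(is.na(null))),
                     class = "rrpp"))
  }
  if (nperm < 1L) stop("nperm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null <- matrix(NA_real_, nperm, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(nperm)) {
    idx <- sample.int(n)
    null[b, ] <- stat_fn(F0 + R0[idx, , drop = FALSE])
  }
  pv <- vapply(seq_along(obs), function(j) pval_count(obs[j], null[, j]),
               numeric(1))
  names(pv) <- names(obs)
  structure(list(observed = obs, pvalues = pv, null = null, nperm = nperm,
                 seed = seed, exact = FALSE,
                 n_degenerate = colSums(is.na(null))),
            class = "rrpp")
}

#' @export
print.rrpp <- function(x, digits = 4, ...) {
  cat("RRPP with", x$nperm, if (isTRUE(x$exact)) "(exact)" else "random",
      "permutations\n")
  print(data.frame(statistic = names(x$observed),
                   observed = round(x$observed, digits),
                   P = round(x$pvalues, digits)), row.names = FALSE)
  if (any(x$n_degenerate > 0))
    cat("note:", max(x$n_degenerate),
        "permutation(s) produced degenerate statistics (counted in tail)\n")
  invisible(x)
}

#' Bonferroni decisions at an experiment-wise error rate
#'
#' @param p vector of p-values forming one family.
#' @param alpha experiment-wise error rate (default 0.05).
#' @param m family size (defaults to `length(p)`).
#' @return character vector, `"*"` where p <= alpha / m, `"NS"` otherwise.
#' @export
bonferroni_decisions <- function(p, alpha = 0.05, m = length(p)) {
  ifelse(p <= alpha / m, "*", "NS")
}
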