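#' Test parallel character displacement from landmark data
#'
#' The flagship analysis: superimposes the landmark data (separate-subset
#' Procrustes if the dataset carries a partition), fits the full factorial
#' multivariate linear model `~ species * locality * transect` to the
#' tangent-space shape variables, extracts the allopatry-to-sympatry
#' evolution vector for each species x transect, and assesses vector
#' magnitudes and orientations by residual randomization (RRPP):
#'
#' \itemize{
#'   \item within-species pairwise magnitude differences and angles, and
#'     the Var_size / Var_orient heterogeneity summaries, against the
#'     reduced model lacking only the species x locality x transect
#'     interaction;
#'   \item the between-species angle against a reduced model additionally
#'     lacking species x locality, i.e. the null that the two species
#'     share one displacement vector.
#' }
#'
#' Within-species decisions use Bonferroni correction with family size
#' equal to the number of transect pairs per species per statistic type.
#'
#' @param data a `landmark_dataset` (from [assemble_dataset()] or
#'   [simulate_shapes()]), or an n x p `shape_matrix` (then `factors` is
#'   required).
#' @param factors specimen factor data frame when `data` is a shape
#'   matrix.
#' @param partition optional [landmark_partition()] overriding the one in
#'   the dataset.
#' @param model core model formula (default the full factorial).
#' @param nperm number of RRPP permutations (9,999 reproduces the default
#'   study design; smaller values are fine for exploration).
#' @param seed integer seed for the permutation streams.
#' @param include_sex add sex as a main effect (no interactions);
#'   specimens of unknown sex are dropped for that model.
#' @param alpha experiment-wise error rate for Bonferroni decisions.
#' @param size_method,orient_method variance-summary definitions, see
#'   [variance_summaries()].
#' @param reduced optional reduced-model formula for the within-species
#'   RRPP null (default: the full model minus the three-way interaction).
#'   A stricter alternative for testing transect homogeneity of vectors is
#'   to drop `locality:transect` as well; see the methods vignette for the
#'   calibration trade-offs.
#' @param sscp SSCP type for the MANOVA table, see [shape_model()].
#' @return an object of class `displacement_analysis` with `print`,
#'   `summary`, `plot`, `coef`, `fitted` and `residuals` methods.
#' @examples
#' sim <- simulate_shapes(sim_spec(n_per_cell = 8, seed = 7))
#' fit <- displacement_analysis(sim$dataset, nperm = 99, seed = 1)
#' summary(fit)
#' @export
displacement_analysis <- function(data, factors = NULL, partition = NULL,
                                  model = ~ species * locality * transect,
                                  nperm = 999L, seed = NULL,
                                  include_sex = FALSE, alpha = 0.05,
                                  size_method = "pooled_magnitude",
                                  orient_method = "pooled_angles",
                                  reduced = NULL,
                                  sscp = "sequential") {
  if (inherits(data, "landmark_dataset")) {
    Y <- separate_subset_shape(data, partition %||% data$partition)
    factors <- data$factors
  } else {
    Y <- data
    if (is.null(factors)) stop("factors required when data is a shape matrix",
                               call. = FALSE)
  }
  if (include_sex) {
    keep <- factors$sex != "unknown"
    if (!all(keep)) {
      message("dropping ", sum(!keep), " specimen(s) of unknown sex")
      Y <- Y[keep, , drop = FALSE]
      factors <- droplevels(factors[keep, , drop = FALSE])
    }
    full <- stats::update(model, ~ . + sex)
  } else full <- model
  fit <- shape_model(Y, factors, full, sscp = sscp)
  manova <- anova.shape_model(fit)
  lsmop <- ls_means_operator(fit)
  lsm <- structure(lsmop %*% as.matrix(Y), cells = attr(lsmop, "cells"),
                   class = c("ls_means", "matrix"))
  vectors <- evolution_vectors(lsm)
  G <- vectors$D %*% lsmop
  stat_all <- make_vector_stats(G, vectors$species, vectors$transect,
                                size_method, orient_method)
  stat_between <- make_between_stat(G, vectors$species)
  reduced <- reduced %||% stats::update(full, ~ . - species:locality:transect)
  reduced_b <- stats::update(
    stats::update(full, ~ . - species:locality:transect), ~ . - species:locality)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rr <- rrpp(as.matrix(Y), factors, full, reduced, stat_all, nperm = nperm)
  rr_b <- rrpp(as.matrix(Y), factors, full, reduced_b, stat_between,
               nperm = nperm)
  obs <- stat_all(as.matrix(Y))
  pw <- pairwise_vector_stats(vectors)
  pw$MD_p <- rr$pvalues[paste0("MD.", pw$species, ".", pw$pair)]
  pw$theta_p <- rr$pvalues[paste0("theta.", pw$species, ".", pw$pair)]
  for (sp in unique(pw$species)) {
    sel <- pw$species == sp
    pw$MD_decision[sel] <- bonferroni_decisions(pw$MD_p[sel], alpha)
    pw$theta_decision[sel] <- bonferroni_decisions(pw$theta_p[sel], alpha)
  }
  rownames(pw) <- NULL
  variance <- data.frame(
    statistic = c("Var_size", "Var_orient"),
    value = unname(obs[c("Var_size", "Var_orient")]),
    P = unname(rr$pvalues[c("Var_size", "Var_orient")]))
  between <- list(angle = unname(rr_b$observed["between_angle"]),
                  P = unname(rr_b$pvalues["between_angle"]))
  structure(list(shapes = Y, factors = factors, formula = full, fit = fit,
                 manova = manova, ls_means = lsm, vectors = vectors,
                 pairwise = pw, variance = variance, between = between,
                 rrpp = rr, rrpp_between = rr_b, nperm = nperm, seed = seed,
                 alpha = alpha, call = match.call()),
            class = "displacement_analysis")
}

# fast closures over the LS-mean difference operator G (vectors x n):
# every statistic is recomputed from G %*% Ystar, i.e. a full-model refit
make_vector_stats <- function(G, species, transect, size_method,
                              orient_method) {
  pairs <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (b > a)
      pairs[[length(pairs) + 1L]] <- c(idx[a], idx[b])
  }
  P <- do.call(rbind, pairs)
  pair_sp <- species[P[, 1]]
  pair_lab <- paste(transect[P[, 1]], transect[P[, 2]], sep = "-")
  spf <- factor(species)
  pair_spf <- factor(pair_sp)
  nm <- c(paste0("MD.", pair_sp, ".", pair_lab),
          paste0("theta.", pair_sp, ".", pair_lab),
          "Var_size", "Var_orient")
  function(Ystar) {
    delta <- G %*% Ystar
    mags <- sqrt(rowSums(delta^2))
    md <- abs(mags[P[, 1]] - mags[P[, 2]])
    dn <- delta / mags
    d1 <- dn[P[, 1], , drop = FALSE]; d2 <- dn[P[, 2], , drop = FALSE]
    th <- 2 * atan2(sqrt(rowSums((d1 - d2)^2)),
                    sqrt(rowSums((d1 + d2)^2))) * 180 / pi
    th[mags[P[, 1]] * mags[P[, 2]] == 0] <- NA_real_
    vs <- if (size_method == "pooled_magnitude") {
      dev <- mags - stats::ave(mags, spf)
      sum(dev^2) / (length(mags) - nlevels(spf))
    } else stats::var(md)
    vo <- if (orient_method == "pooled_angles") stats::var(th)
    else {
      dev <- th - stats::ave(th, pair_spf)
      sum(dev^2) / (length(th) - nlevels(pair_spf))
    }
    stats::setNames(c(md, th, vs, vo), nm)
  }
}

make_between_stat <- function(G, species) {
  spf <- factor(species)
  A <- stats::model.matrix(~ spf - 1)
  A <- t(A) / colSums(A)
  function(Ystar) {
    m <- A %*% (G %*% Ystar)
    c(between_angle = angle_deg(m[1, ], m[2, ]))
  }
}

#' @export
print.displacement_analysis <- function(x, digits = 4, ...) {
  cat("Parallel character displacement analysis (RRPP, ", x$nperm,
      " permutations)\n", sep = "")
  cat("  n =", nrow(x$shapes), "specimens, p =", ncol(x$shapes),
      "shape variables\n")
  cat("  vector magnitudes:\n")
  print(data.frame(species = x$vectors$species,
                   transect = x$vectors$transect,
                   d = round(x$vectors$magnitude, digits)), row.names = FALSE)
  cat("  Var_size = ", format(x$variance$value[1], digits = digits),
      " (P = ", format(x$variance$P[1], digits = digits), "); Var_orient = ",
      format(x$variance$value[2], digits = digits),
      " (P = ", format(x$variance$P[2], digits = digits), ")\n", sep = "")
  cat("  between-species angle = ", round(x$between$angle, 2),
      " degrees (P = ", format(x$between$P, digits = digits), ")\n", sep = "")
  invisible(x)
}

# square matrix per species: lower triangle observed, upper triangle
# p-values with NS flags (the layout of the classic pairwise table)
pairwise_table_matrix <- function(pw, vectors, stat = c("MD", "theta")) {
  stat <- match.arg(stat)
  out <- list()
  for (sp in unique(pw$species)) {
    tr <- unique(vectors$transect)
    m <- matrix("", length(tr), length(tr), dimnames = list(tr, tr))
    sel <- pw[pw$species == sp, ]
    for (r in seq_len(nrow(sel))) {
      ij <- strsplit(sel$pair[r], "-")[[1]]
      obs <- sel[[stat]][r]
      pv <- sel[[paste0(stat, "_p")]][r]
      dec <- sel[[paste0(stat, "_decision")]][r]
      m[ij[2], ij[1]] <- format(round(obs, 5), nsmall = 4)
      m[ij[1], ij[2]] <- paste0(format(round(pv, 4), nsmall = 4),
                                if (dec == "NS") " NS" else "")
    }
    out[[sp]] <- m
  }
  out
}

#' @export
summary.displacement_analysis <- function(object, ...) {
  structure(list(x = object), class = "summary.displacement_analysis")
}

#' @export
print.summary.displacement_analysis <- function(x, ...) {
  obj <- x$x
  print(obj$manova)
  cat("\nPairwise comparisons of evolutionary vectors",
      "(lower triangle: observed; upper: RRPP P, NS = not significant",
      sprintf("after Bonferroni at alpha = %.2f)\n", obj$alpha))
  for (stat in c("MD", "theta")) {
    cat("\n", if (stat == "MD") "Vector magnitude differences"
        else "Vector orientations (degrees)", "\n", sep = "")
    tabs <- pairwise_table_matrix(obj$pairwise, obj$vectors, stat)
    for (sp in names(tabs)) {
      cat(" species:", sp, "\n")
      print(tabs[[sp]], quote = FALSE)
    }
  }
  cat("\nVariance summaries:\n")
  print(data.frame(statistic = obj$variance$statistic,
                   value = signif(obj$variance$value, 6),
                   P = round(obj$variance$P, 4)), row.names = FALSE)
  cat("\nBetween-species angle:", round(obj$between$angle, 2),
      "degrees, P =", format(obj$between$P, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.displacement_analysis <- function(object, ...) coef(object$fit)
#' @export
fitted.displacement_analysis <- function(object, ...) fitted(object$fit)
#' @export
residuals.displacement_analysis <- function(object, ...) residuals(object$fit)

#' @export
plot.displacement_analysis <- function(x, ...) {
  pca <- shape_pca(x$shapes)
  trajectory_plot(pca, x$ls_means, x$vectors, x$factors, ...)
}
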