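# factorial multivariate linear model: design, fit, MANOVA table, LS means

#' Build an effect-coded factorial design matrix
#'
#' Uses sum-to-zero (effect) coding for every factor so that least-squares
#' cell means are the natural model predictions.  The returned matrix
#' carries a term -> column map.  Rank deficiency (e.g. an empty design
#' cell making an interaction inestimable) is reported with the name of
#' the first offending term.
#'
#' @param factors data frame of specimen factors.
#' @param formula model formula, e.g. `~ species * locality * transect`.
#' @return list with `X` (model matrix), `assign` (column -> term index),
#'   `term_labels`, `terms` (terms object), and `xlev` (factor levels).
#' @export
build_design <- function(factors, formula = ~ species * locality * transect) {
  tt <- stats::terms(formula)
  mf <- stats::model.frame(tt, factors, drop.unused.levels = TRUE)
  fvars <- names(mf)[vapply(mf, is.factor, logical(1))]
  contr <- stats::setNames(as.list(rep("contr.sum", length(fvars))), fvars)
  X <- stats::model.matrix(tt, mf, contrasts.arg = contr)
  asgn <- attr(X, "assign")
  labels <- attr(tt, "term.labels")
  # sequential rank check: adding each term block must add its full rank
  r_prev <- 0L
  for (j in seq_along(labels)) {
    cols <- which(asgn <= j)
    r <- qr(X[, cols, drop = FALSE])$rank
    if (r - r_prev < sum(asgn == j))
      stop("design is rank deficient at term '", labels[j],
           "' (empty or confounded cells)", call. = FALSE)
    r_prev <- r
  }
  list(X = X, assign = asgn, term_labels = labels, terms = tt,
       xlev = lapply(mf, levels))
}

# least-squares engine: QR fit of multivariate responses
fit_mlm <- function(Y, X) {
  fit <- stats::lm.fit(X, Y)
  if (any(is.na(fit$coefficients)))
    stop("singular normal equations in multivariate fit", call. = FALSE)
  res <- as.matrix(fit$residuals)   # lm.fit drops the dim of an n x 1 response
  list(coefficients = as.matrix(fit$coefficients),
       fitted = Y - res,
       residuals = res,
       rank = fit$rank)
}

#' Fit the factorial multivariate linear model for shape
#'
#' Least-squares fit of an n x p shape-variable matrix on an effect-coded
#' factorial design.  The fitted object supports `coef`, `fitted`,
#' `residuals`, `anova` (the MANOVA table) and [ls_means()].
#'
#' @param Y an n x p `shape_matrix` (or plain matrix) of responses.
#' @param factors data frame of specimen factors aligned with the rows of
#'   `Y`.
#' @param formula model formula (default the full factorial
#'   `~ species * locality * transect`).
#' @param sscp `"sequential"` (Type I, terms in formula order; the
#'   default) or `"marginal"` (each term dropped from the full model).
#' @return an object of class `shape_model`.
#' @export
shape_model <- function(Y, factors,
                        formula = ~ species * locality * transect,
                        sscp = c("sequential", "marginal")) {
  sscp <- match.arg(sscp)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(factors))
    stop("Y and factors disagree on specimen count", call. = FALSE)
  d <- build_design(factors, formula)
  n <- nrow(Y)
  if (n <= ncol(d$X))
    stop("need n > ", ncol(d$X), " specimens to fit this model", call. = FALSE)
  fit <- fit_mlm(Y, d$X)
  structure(c(fit, list(Y = Y, design = d, factors = factors,
                        formula = formula, sscp = sscp,
                        df_residual = n - fit$rank)),
            class = "shape_model")
}

#' @export
coef.shape_model <- function(object, ...) object$coefficients
#' @export
fitted.shape_model <- function(object, ...) object$fitted
#' @export
residuals.shape_model <- function(object, ...) object$residuals

#' @export
print.shape_model <- function(x, ...) {
  cat("Multivariate linear model for shape\n")
  cat("  formula: ", deparse(x$formula), "\n")
  cat("  n =", nrow(x$Y), ", p =", ncol(x$Y),
      ", residual df =", x$df_residual, "\n")
  invisible(x)
}

# Pillai's trace and its standard F approximation:
#   s = min(df_h, p), m = (|df_h - p| - 1)/2, u = (df_e - p - 1)/2
#   F = (2u + s + 1)/(2m + s + 1) * V / (s - V),
#   df1 = s(2m + s + 1), df2 = s(2u + s + 1)
pillai_f <- function(V, df_h, df_e, p) {
  s <- min(df_h, p)
  m <- (abs(df_h - p) - 1) / 2
  u <- (df_e - p - 1) / 2
  Fstat <- (2 * u + s + 1) / (2 * m + s + 1) * V / (s - V)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * u + s + 1)
  c(F = Fstat, df1 = df1, df2 = df2,
    p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' MANOVA table with Pillai's trace
#'
#' Per model term, the hypothesis SSCP matrix H (sequential: difference of
#' projections of nested fits in formula order; marginal: the term dropped
#' from the full model) and the residual SSCP E give Pillai's trace
#' V = trace(H (H + E)^-1), with the standard F approximation (see
#' `pillai_f` in the source for the exact form).
#'
#' @param object a `shape_model`.
#' @param ... unused.
#' @return a data frame of class `manova_table` with one row per term:
#'   Df, Pillai, approx.F, num.Df, den.Df, P.
#' @export
anova.shape_model <- function(object, ...) {
  Y <- object$Y
  p <- ncol(Y)
  X <- object$design$X
  asgn <- object$design$assign
  labels <- object$design$term_labels
  df_e <- object$df_residual
  if (p >= df_e + 1)
    stop("residual SSCP is singular (p >= residual df); reduce the shape ",
         "dimension or increase n", call. = FALSE)
  E <- crossprod(object$residuals)
  rows <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    if (object$sscp == "sequential") {
      f1 <- fit_mlm(Y, X[, asgn <= j, drop = FALSE])$fitted
      f0 <- fit_mlm(Y, X[, asgn <= j - 1L, drop = FALSE])$fitted
    } else {
      f1 <- object$fitted
      f0 <- fit_mlm(Y, X[, asgn != j, drop = FALSE])$fitted
    }
    H <- crossprod(f1 - f0)
    df_h <- sum(asgn == j)
    V <- if (sum(diag(H)) <= 1e-24 * max(sum(Y^2), 1)) 0
    else sum(diag(solve(H + E, H)))
    fr <- pillai_f(V, df_h, df_e, p)
    rows[[j]] <- data.frame(term = labels[j], Df = df_h, Pillai = V,
                            approx.F = fr["F"], num.Df = fr["df1"],
                            den.Df = fr["df2"], P = fr["p"],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("manova_table", "data.frame")
  attr(out, "sscp") <- object$sscp
  out
}

#' @export
print.manova_table <- function(x, digits = 4, ...) {
  cat("MANOVA (Pillai's trace, ", attr(x, "sscp"), " SSCP)\n", sep = "")
  df <- data.frame(Factor = x$term, Df = x$Df,
                   `Pillai's Trace` = round(x$Pillai, digits),
                   `Approx. F` = round(x$approx.F, digits),
                   `Df_num, Df_denom` = sprintf("%d, %d", as.integer(x$num.Df),
                                                as.integer(x$den.Df)),
                   P = format.pval(x$P, digits = digits),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Least-squares (model-predicted) cell means
#'
#' Predictions of the fitted factorial model at each species x locality x
#' transect cell.  With effect coding, any additional model factors (e.g.
#' sex) are averaged over their levels, i.e. held at their balanced
#' values.  For a balanced design with the full factorial model these
#' equal the raw cell means.
#'
#' @param object a `shape_model`.
#' @param cells optional data frame of cells to predict (defaults to the
#'   full species x locality x transect grid).
#' @return a matrix of cell means (cells x p) of class `ls_means` with a
#'   `cells` attribute.
#' @export
ls_means <- function(object, cells = NULL) {
  d <- object$design
  xlev <- d$xlev
  core <- intersect(c("species", "locality", "transect"), names(xlev))
  if (is.null(cells)) {
    cells <- expand.grid(lapply(xlev[core], identity),
                         stringsAsFactors = TRUE)
  }
  extra <- setdiff(names(xlev), names(cells))
  grid <- cells
  if (length(extra)) {
    full <- expand.grid(c(lapply(cells, unique), xlev[extra]),
                        stringsAsFactors = TRUE)
    # rebuild in the same cell order
    grid <- merge(cbind(cells, .cell = seq_len(nrow(cells))), full,
                  by = names(cells), sort = FALSE)
  } else grid$.cell <- seq_len(nrow(cells))
  for (v in names(xlev)) grid[[v]] <- factor(grid[[v]], levels = xlev[[v]])
  fvars <- names(xlev)
  contr <- stats::setNames(as.list(rep("contr.sum", length(fvars))), fvars)
  Xc <- stats::model.matrix(stats::delete.response(d$terms), grid,
                            contrasts.arg = contr, xlev = xlev)
  pred <- Xc %*% object$coefficients
  out <- rowsum(pred, grid$.cell) / as.vector(table(grid$.cell))
  out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  rownames(out) <- do.call(paste, c(cells[core], list(sep = ".")))
  structure(out, cells = cells[core], class = c("ls_means", "matrix"))
}

# cells x n linear map Y -> LS means for fixed design (used by RRPP so the
# full model need not be refit explicitly in each permutation)
ls_means_operator <- function(object) {
  d <- object$design
  X <- d$X
  xlev <- d$xlev
  core <- intersect(c("species", "locality", "transect"), names(xlev))
  cells <- expand.grid(lapply(xlev[core], identity), stringsAsFactors = TRUE)
  lm_attr <- ls_means(object, cells)
  # Xc averaged over extra factors, reproduced here as a matrix operator
  coefop <- solve(crossprod(X), t(X))          # (q x n): Y -> coefficients
  # build averaged prediction rows by differencing ls_means against coef map
  # directly: LS means = Xc_avg %*% coef, so operator = Xc_avg %*% coefop
  grid <- cells; grid$.cell <- seq_len(nrow(cells))
  extra <- setdiff(names(xlev), names(cells))
  if (length(extra)) {
    full <- expand.grid(c(lapply(cells, unique), xlev[extra]),
                        stringsAsFactors = TRUE)
    grid <- merge(cbind(cells, .cell = seq_len(nrow(cells))), full,
                  by = names(cells), sort = FALSE)
  }
  for (v in names(xlev)) grid[[v]] <- factor(grid[[v]], levels = xlev[[v]])
  contr <- stats::setNames(as.list(rep("contr.sum", length(xlev))), names(xlev))
  Xc <- stats::model.matrix(stats::delete.response(d$terms), grid,
                            contrasts.arg = contr, xlev = xlev)
  Xc_avg <- rowsum(Xc, grid$.cell) / as.vector(table(grid$.cell))
  Xc_avg <- Xc_avg[order(as.integer(rownames(Xc_avg))), , drop = FALSE]
  op <- Xc_avg %*% coefop
  rownames(op) <- rownames(lm_attr)
  attr(op, "cells") <- cells
  op
}
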