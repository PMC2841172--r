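make_factors <- function(n_per_cell = 2, transects = 3) {
  g <- expand.grid(species = c("a", "b"),
                   locality = c("allopatric", "sympatric"),
                   transect = paste0("T", seq_len(transects)),
                   rep = seq_len(n_per_cell))
  data.frame(specimen_id = sprintf("s%03d", seq_len(nrow(g))),
             species = g$species, locality = g$locality,
             transect = g$transect,
             sex = rep(c("male", "female"), length.out = nrow(g)))
}

test_that("effect-coded design matrices have the expected structure", {
  fac <- normalize_factors(make_factors())
  d <- build_design(fac)
  expect_equal(ncol(d$X), 12L)  # 1+1+1+2+1+2+2+2
  expect_equal(length(d$term_labels), 7L)
  d1 <- build_design(fac, ~ species)
  expect_equal(ncol(d1$X), 2L)
  # effect coding: columns sum to zero over a balanced design
  expect_lt(max(abs(colSums(d$X[, -1]))), 1e-12)
  # empty cell: drop one species x transect combination entirely
  bad <- fac[!(fac$species == "a" & fac$transect == "T1"), ]
  expect_error(build_design(droplevels(bad)), "rank deficient")
})

test_that("the least-squares engine is exact", {
  fac <- normalize_factors(make_factors(3))
  d <- build_design(fac)
  set.seed(5)
  beta <- matrix(rnorm(12 * 4), 12, 4)
  Y <- d$X %*% beta
  fit <- morphodisp:::fit_mlm(Y, d$X)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$coefficients, beta, tolerance = 1e-8, ignore_attr = TRUE)
  # intercept-only fits the column means
  Y2 <- Y + matrix(rnorm(length(Y)), nrow(Y))
  f0 <- morphodisp:::fit_mlm(Y2, matrix(1, nrow(Y2), 1))
  expect_equal(f0$fitted[1, ], colMeans(Y2), ignore_attr = TRUE)
  # random problem matches the normal-equations oracle
  f2 <- morphodisp:::fit_mlm(Y2, d$X)
  beta_oracle <- solve(crossprod(d$X), crossprod(d$X, Y2))
  expect_equal(f2$coefficients, beta_oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(d$X, f2$residuals))), 1e-8)
})

test_that("Pillai's trace matches stats::manova and the eigenvalue oracle", {
  fac <- normalize_factors(make_factors(4))
  set.seed(8)
  Y <- matrix(rnorm(nrow(fac) * 3), ncol = 3)
  Y[fac$species == "a", 1] <- Y[fac$species == "a", 1] + 1
  Y[fac$locality == "sympatric", 2] <- Y[fac$locality == "sympatric", 2] + 0.5
  fit <- shape_model(Y, fac)
  tab <- anova(fit)
  oracle <- summary(stats::manova(Y ~ species * locality * transect,
                                  data = fac), test = "Pillai")$stats
  for (j in seq_len(nrow(tab))) {
    expect_equal(tab$Pillai[j], oracle[j, "Pillai"], tolerance = 1e-10)
    expect_equal(tab$approx.F[j], oracle[j, "approx F"], tolerance = 1e-8)
    expect_equal(unname(tab$num.Df[j]), unname(oracle[j, "num Df"]))
    expect_equal(unname(tab$den.Df[j]), unname(oracle[j, "den Df"]))
    expect_equal(tab$P[j], oracle[j, "Pr(>F)"], tolerance = 1e-8)
  }
  # single-term, two-group bivariate data: V = sum lambda/(1+lambda)
  fac2 <- fac[, c("specimen_id", "species")]
  Y2 <- Y[, 1:2]
  fit2 <- shape_model(Y2, fac2, ~ species)
  tab2 <- anova(fit2)
  X2 <- build_design(fac2, ~ species)$X
  H <- crossprod(morphodisp:::fit_mlm(Y2, X2)$fitted -
                   morphodisp:::fit_mlm(Y2, X2[, 1, drop = FALSE])$fitted)
  E <- crossprod(morphodisp:::fit_mlm(Y2, X2)$residuals)
  lam <- eigen(solve(E) %*% H, only.values = TRUE)$values
  expect_equal(tab2$Pillai[1], sum(Re(lam) / (1 + Re(lam))), tolerance = 1e-10)
})

test_that("one response degenerates to univariate ANOVA", {
  fac <- normalize_factors(make_factors(3))
  set.seed(9)
  y <- rnorm(nrow(fac)) + 2 * (fac$species == "a")
  tab <- anova(shape_model(matrix(y), fac))
  uni <- anova(lm(y ~ species * locality * transect, data = fac))
  expect_equal(tab$approx.F, uni$`F value`[seq_len(nrow(tab))],
               tolerance = 1e-10)
  expect_equal(tab$P, uni$`Pr(>F)`[seq_len(nrow(tab))], tolerance = 1e-10)
})

test_that("sequential SSCPs and the residual SSCP sum to the total", {
  fac <- normalize_factors(make_factors(3))
  set.seed(10)
  Y <- matrix(rnorm(nrow(fac) * 4), ncol = 4)
  fit <- shape_model(Y, fac)
  X <- fit$design$X
  asgn <- fit$design$assign
  total <- crossprod(scale(Y, scale = FALSE))
  acc <- crossprod(fit$residuals)
  for (j in seq_along(fit$design$term_labels)) {
    f1 <- morphodisp:::fit_mlm(Y, X[, asgn <= j, drop = FALSE])$fitted
    f0 <- morphodisp:::fit_mlm(Y, X[, asgn <= j - 1, drop = FALSE])$fitted
    acc <- acc + crossprod(f1 - f0)
  }
  expect_equal(acc, total, tolerance = 1e-8)
})

test_that("identical responses give zero traces", {
  fac <- normalize_factors(make_factors(2))
  Y <- matrix(1, nrow(fac), 2)
  tab <- anova(shape_model(Y, fac, ~ species))
  expect_equal(tab$Pillai, 0)
})

test_that("parametric MANOVA p-values are uniform under the null", {
  fac <- normalize_factors(make_factors(10, transects = 1))
  set.seed(77)
  ps <- replicate(300, {
    Y <- matrix(rnorm(nrow(fac) * 3), ncol = 3)
    anova(shape_model(Y, fac, ~ species))$P[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("LS means equal raw cell means when balanced, model predictions otherwise", {
  sim <- quick_sim(n_per_cell = 4, seed = 55)
  Y <- separate_subset_shape(sim$dataset)
  fac <- sim$dataset$factors
  fit <- shape_model(Y, fac)
  lsm <- ls_means(fit)
  cells <- attr(lsm, "cells")
  for (i in seq_len(nrow(cells))) {
    sel <- fac$species == cells$species[i] & fac$locality == cells$locality[i] &
      fac$transect == cells$transect[i]
    expect_equal(unname(lsm[i, ]), unname(colMeans(Y[sel, , drop = FALSE])),
                 tolerance = 1e-10)
  }
  # unbalanced: doubling one cell breaks the raw-mean identity but matches
  # an independent lm + predict oracle
  dup <- which(fac$species == fac$species[1] &
                 fac$locality == fac$locality[1] &
                 fac$transect == fac$transect[1])
  Yu <- rbind(as.matrix(Y), as.matrix(Y)[dup, , drop = FALSE])
  facu <- rbind(fac, transform(fac[dup, ],
                               specimen_id = paste0(specimen_id, "_d")))
  fitu <- shape_model(Yu, facu)
  lsmu <- ls_means(fitu)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  lmfit <- lm(Yu ~ species * locality * transect, data = facu)
  pred <- predict(lmfit, newdata = attr(lsmu, "cells"))
  expect_equal(unname(unclass(lsmu)), unname(pred), tolerance = 1e-8,
               ignore_attr = TRUE)
  grand <- colMeans(Yu[facu$species == cells$species[1] &
                         facu$locality == cells$locality[1] &
                         facu$transect == cells$transect[1], , drop = FALSE])
  expect_equal(unname(lsmu[1, ]), unname(grand), tolerance = 1e-10)
})

test_that("the Pillai F approximation reproduces the published df layout", {
  # n = 336, p = 18 gives (18, 307) for 1-df terms and (36, 616) for 2-df
  fr1 <- morphodisp:::pillai_f(0.5, df_h = 1, df_e = 324, p = 18)
  expect_equal(unname(fr1[c("df1", "df2")]), c(18, 307))
  fr2 <- morphodisp:::pillai_f(0.16, df_h = 2, df_e = 324, p = 18)
  expect_equal(unname(fr2[c("df1", "df2")]), c(36, 616))
})
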