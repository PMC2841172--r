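# construct a bare evolution_vectors object for unit-level geometry checks
fake_vectors <- function(delta, species, transect) {
  structure(list(delta = delta, species = species, transect = transect,
                 magnitude = sqrt(rowSums(delta^2))),
            class = "evolution_vectors")
}

test_that("evolution vectors difference the LS means allopatry -> sympatry", {
  sim <- quick_sim(n_per_cell = 4, seed = 61)
  Y <- separate_subset_shape(sim$dataset)
  fit <- shape_model(Y, sim$dataset$factors)
  lsm <- ls_means(fit)
  ev <- evolution_vectors(lsm)
  expect_equal(nrow(ev$delta), 6L)  # 2 species x 3 transects
  expect_equal(ev$magnitude, sqrt(rowSums(ev$delta^2)), tolerance = 1e-12)
  i <- 1L
  sel_s <- which(attr(lsm, "cells")$species == ev$species[i] &
                   attr(lsm, "cells")$transect == ev$transect[i])
  symp <- sel_s[attr(lsm, "cells")$locality[sel_s] == "sympatric"]
  allo <- sel_s[attr(lsm, "cells")$locality[sel_s] == "allopatric"]
  expect_equal(ev$delta[i, ], lsm[symp, ] - lsm[allo, ], ignore_attr = TRUE)
  # allopatric mean == sympatric mean gives the zero vector
  lsm0 <- lsm
  lsm0[symp, ] <- lsm0[allo, ]
  ev0 <- evolution_vectors(structure(lsm0, cells = attr(lsm, "cells"),
                                     class = class(lsm)))
  expect_equal(unname(ev0$magnitude[i]), 0)
})

test_that("pairwise magnitude differences and angles follow the geometry", {
  v <- c(3, 4, 0)
  ev <- fake_vectors(rbind(v, 2 * v, c(0, 0, 5)), rep("sp1", 3),
                     c("A", "B", "C"))
  pw <- pairwise_vector_stats(ev)
  ab <- pw[pw$pair == "A-B", ]
  expect_equal(ab$theta, 0, tolerance = 1e-10)
  expect_equal(ab$MD, 5)
  ac <- pw[pw$pair == "A-C", ]
  expect_equal(ac$theta, 90, tolerance = 1e-10)
  expect_equal(ac$MD, 0)
  ev45 <- fake_vectors(rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5))),
                       rep("sp1", 2), c("A", "B"))
  expect_equal(pairwise_vector_stats(ev45)$theta, 45, tolerance = 1e-10)
  ev0 <- fake_vectors(rbind(c(1, 0), c(0, 0)), rep("sp1", 2), c("A", "B"))
  expect_error(pairwise_vector_stats(ev0), "sp1.B")
})

test_that("between-species angle uses species mean vectors", {
  d <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  ev <- fake_vectors(d, c("s1", "s1", "s2", "s2"), c("A", "B", "A", "B"))
  expect_equal(between_species_angle(ev), 90, tolerance = 1e-10)
  ev_same <- fake_vectors(d[c(1, 2, 1, 2), ], c("s1", "s1", "s2", "s2"),
                          c("A", "B", "A", "B"))
  expect_equal(between_species_angle(ev_same), 0)
})

test_that("variance summaries match hand computation and vanish for parallel vectors", {
  # species 1 magnitudes 0.04/0.05/0.06 along one axis; species 2 all 0.05
  d <- rbind(0.04 * c(1, 0, 0), 0.05 * c(1, 0, 0), 0.06 * c(1, 0, 0),
             0.05 * c(0, 1, 0), 0.05 * c(0, 1, 0), 0.05 * c(0, 1, 0))
  ev <- fake_vectors(d, rep(c("s1", "s2"), each = 3), rep(c("A", "B", "C"), 2))
  vs <- variance_summaries(ev)
  # pooled SS = (1e-4 + 0 + 1e-4) over df = 6 - 2
  expect_equal(unname(vs["Var_size"]), 5e-5, tolerance = 1e-12)
  expect_equal(unname(vs["Var_orient"]), 0, tolerance = 1e-10)
  ev_par <- fake_vectors(d[c(2, 2, 2, 4, 4, 4), ], rep(c("s1", "s2"), each = 3),
                         rep(c("A", "B", "C"), 2))
  vsp <- variance_summaries(ev_par)
  expect_equal(unname(vsp), c(0, 0), tolerance = 1e-12)
  # alternative readings stay finite and nonnegative
  vs2 <- variance_summaries(ev, size_method = "pairwise_md",
                            orient_method = "within_species")
  expect_true(all(vs2 >= 0))
})

test_that("the RRPP counting rule includes the observed arrangement", {
  expect_equal(morphodisp:::pval_count(5, rep(1, 9)), 1 / 10)
  expect_equal(morphodisp:::pval_count(5, c(rep(1, 8), 5)), 2 / 10)
  expect_equal(morphodisp:::pval_count(5, rep(6, 9)), 1)
  # NA (degenerate) permutations count towards the tail
  expect_equal(morphodisp:::pval_count(5, c(rep(1, 8), NA)), 2 / 10)
})

test_that("Monte-Carlo RRPP converges to the exact enumeration", {
  set.seed(123)
  y <- c(rnorm(3), rnorm(3, mean = 1.2))
  g <- factor(rep(c("a", "b"), each = 3))
  fac <- data.frame(g = g)
  stat_fn <- function(Ystar)
    c(md = abs(mean(Ystar[g == "a", 1]) - mean(Ystar[g == "b", 1])))
  ex <- rrpp(matrix(y), fac, ~ g, ~ 1, stat_fn, exact = TRUE)
  expect_equal(ex$nperm, 720L)
  p_oracle <- enum_rrpp_pvalue(y, g)
  expect_equal(unname(ex$pvalues), p_oracle, tolerance = 1e-12)
  mc <- rrpp(matrix(y), fac, ~ g, ~ 1, stat_fn, nperm = 4999, seed = 5)
  se <- sqrt(p_oracle * (1 - p_oracle) / 4999)
  expect_lt(abs(unname(mc$pvalues) - p_oracle), 2 * se + 1e-3)
})

test_that("RRPP is deterministic under a seed", {
  sim <- quick_sim(n_per_cell = 3, seed = 91)
  a1 <- displacement_analysis(sim$dataset, nperm = 49, seed = 7)
  a2 <- displacement_analysis(sim$dataset, nperm = 49, seed = 7)
  expect_identical(a1$pairwise, a2$pairwise)
  expect_identical(a1$between, a2$between)
  a3 <- displacement_analysis(sim$dataset, nperm = 49, seed = 8)
  expect_false(identical(a1$pairwise$MD_p, a3$pairwise$MD_p))
})

test_that("vector statistics are invariant to orthonormal rotations of shape space", {
  sim <- quick_sim(n_per_cell = 4, seed = 71)
  Y <- as.matrix(separate_subset_shape(sim$dataset))
  fac <- sim$dataset$factors
  ev1 <- evolution_vectors(ls_means(shape_model(Y, fac)))
  Q <- rand_rotation(ncol(Y), seed = 2)
  ev2 <- evolution_vectors(ls_means(shape_model(Y %*% Q, fac)))
  expect_equal(ev1$magnitude, ev2$magnitude, tolerance = 1e-8)
  pw1 <- pairwise_vector_stats(ev1)
  pw2 <- pairwise_vector_stats(ev2)
  expect_equal(pw1$theta, pw2$theta, tolerance = 1e-8)
  expect_equal(pw1$MD, pw2$MD, tolerance = 1e-10)
  expect_equal(between_species_angle(ev1), between_species_angle(ev2),
               tolerance = 1e-8)
  # Pillai's trace shares the invariance
  expect_equal(anova(shape_model(Y, fac))$Pillai,
               anova(shape_model(Y %*% Q, fac))$Pillai, tolerance = 1e-8)
})

test_that("Bonferroni decisions respect the family size", {
  expect_equal(bonferroni_decisions(0.0166, alpha = 0.05, m = 3), "*")
  expect_equal(bonferroni_decisions(0.03, alpha = 0.05, m = 3), "NS")
  expect_equal(bonferroni_decisions(0.03, alpha = 0.05, m = 1), "*")
  expect_equal(bonferroni_decisions(c(0.01, 0.04, 0.2), alpha = 0.05),
               c("*", "NS", "NS"))
})

test_that("power is monotone in the true divergence angle", {
  angles <- c(0, 30, 60, 90)
  rej <- sapply(angles, function(ang) {
    hits <- 0L
    for (r in 1:25) {
      spec <- if (ang == 0)
        sim_spec(n_per_cell = 15, scenario = "parallel", between_angle = 0,
                 seed = 500 + r)
      else sim_spec(n_per_cell = 15, scenario = "divergent",
                    within_angle = ang, seed = 500 + r)
      sim <- simulate_shapes(spec)
      a <- displacement_analysis(sim$dataset, nperm = 99, seed = r)
      hits <- hits + any(a$pairwise$theta_p <= 0.05)
    }
    hits / 25
  })
  # non-decreasing up to sampling error: compare ends
  expect_lte(rej[1], rej[3] + 0.1)
  expect_lte(rej[2], rej[4] + 0.1)
  expect_gt(rej[4], rej[1])
})
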