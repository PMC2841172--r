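test_that("PCA recovers degenerate and isotropic structure", {
  set.seed(3)
  t_ <- rnorm(30)
  line <- cbind(2 * t_, -t_, 0.5 * t_) + 5
  p <- shape_pca(line)
  expect_equal(p$explained[1], 1, tolerance = 1e-10)
  # completeness: reconstruction from all PCs
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, sweep(line, 2, colMeans(line)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # isotropy: explained fractions near 1/p
  set.seed(4)
  iso <- matrix(rnorm(4000 * 5), ncol = 5)
  pi_ <- shape_pca(iso)
  expect_lt(max(abs(pi_$explained - 0.2)), 0.03)
  # scores are uncorrelated and the sign convention is deterministic
  expect_lt(max(abs(cov(pi_$scores)[upper.tri(diag(5))])), 1e-10)
  for (j in 1:5) expect_gt(pi_$loadings[which.max(abs(pi_$loadings[, j])), j], 0)
})

test_that("full PC scores are a rigid rotation of shape space", {
  sim <- quick_sim(n_per_cell = 4, seed = 81)
  Y <- as.matrix(separate_subset_shape(sim$dataset))
  p <- shape_pca(Y)
  d1 <- dist(Y)
  d2 <- dist(p$scores)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-8)
})

test_that("trajectory_plot returns the plotted geometry", {
  sim <- quick_sim(n_per_cell = 4, seed = 82)
  Y <- separate_subset_shape(sim$dataset)
  fit <- shape_model(Y, sim$dataset$factors)
  lsm <- ls_means(fit)
  ev <- evolution_vectors(lsm)
  pca <- shape_pca(Y)
  pdf(NULL); on.exit(dev.off())
  drawn <- trajectory_plot(pca, lsm, ev, sim$dataset$factors)
  expect_equal(nrow(drawn$arrows), 6L)
  expect_equal(nrow(drawn$ls_scores), 12L)
  # arrows connect the projected allopatric and sympatric LS means
  cells <- attr(lsm, "cells")
  proj <- sweep(unclass(lsm), 2, pca$center) %*% pca$loadings[, 1:2]
  a1 <- drawn$arrows[1, ]
  ai <- which(cells$species == a1$species & cells$transect == a1$transect &
                cells$locality == "allopatric")
  expect_equal(c(a1$x0, a1$y0), unname(proj[ai, ]), tolerance = 1e-12)
  # points-only plot with no vectors
  drawn0 <- trajectory_plot(pca, lsm, NULL, sim$dataset$factors)
  expect_null(drawn0$arrows)
})

test_that("parallel simulations plot near-parallel within-species arrows", {
  sim <- quick_sim(n_per_cell = 25, seed = 83)
  a <- displacement_analysis(sim$dataset, nperm = 9, seed = 1)
  pdf(NULL); on.exit(dev.off())
  drawn <- plot(a)
  ar <- drawn$arrows
  for (sp in unique(ar$species)) {
    v <- ar[ar$species == sp, ]
    dirs <- cbind(v$x1 - v$x0, v$y1 - v$y0)
    angs <- apply(dirs, 1, function(z) atan2(z[2], z[1])) * 180 / pi
    expect_lt(max(angs) - min(angs), 45)
  }
})

test_that("deformation grids scale with exaggeration and report bending energy", {
  sim <- quick_sim(n_per_cell = 5, seed = 84)
  a <- displacement_analysis(sim$dataset, nperm = 9, seed = 1)
  g1 <- deformation_report(a, exaggeration = 1)
  g3 <- deformation_report(a, exaggeration = 3)
  expect_true(all(vapply(g1, function(g) g$bending_energy >= 0, logical(1))))
  lab <- names(g1)[1]
  d1 <- g1[[lab]]$target - g1[[lab]]$reference
  d3 <- g3[[lab]]$target - g3[[lab]]$reference
  expect_equal(d3, 3 * d1, tolerance = 1e-8)
  # a non-affine target reports positive bending energy
  expect_gt(max(vapply(g3, function(g) g$bending_energy, numeric(1))), 0)
  # consensus target -> identity grid
  ref <- attr(a$shapes, "bases")[[1]]$consensus
  gid <- tps_grid(ref, ref)
  expect_lt(max(abs(gid$warped - gid$grid)), 1e-9)
})

test_that("the pipeline is deterministic and validates inputs", {
  base_cfg <- list(n_per_cell = 3, nperm = 19, seed = 42, k = 8,
                   partition = NULL, nuisance = FALSE)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  run_pipeline(c(base_cfg, out_dir = d1), "all")
  run_pipeline(c(base_cfg, out_dir = d2), "all")
  for (f in c("manova_table.csv", "pairwise_vectors.csv",
              "vector_magnitudes.csv", "variance_summaries.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "run_log.json")))
  log <- jsonlite::read_json(file.path(d1, "run_log.json"))
  expect_equal(log$seed, 42)
  expect_equal(log$nperm, 19)
  expect_error(run_pipeline(list(landmarks = tempfile()), "analyze"),
               "not found")
})
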