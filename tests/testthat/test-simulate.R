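test_that("make_template is deterministic, unit-size and well separated", {
  t1 <- make_template(12)
  expect_identical(t1, make_template(12))
  expect_equal(sqrt(sum(t1^2)), 1, tolerance = 1e-12)
  expect_equal(colMeans(t1), c(0, 0), tolerance = 1e-12)
  expect_gt(min(dist(t1)), 1e-3)
  expect_silent(bending_energy(t1))
  expect_error(make_template(3), "k >= 4")
})

test_that("scenarios build the stated displacement geometry", {
  sc0 <- displacement_scenario("null", k = 12)
  expect_true(all(sc0$magnitudes == 0))

  scp <- displacement_scenario("parallel", k = 12, between_angle = 47.71)
  u <- scp$directions[, 1, 1]; v <- scp$directions[, 1, 2]
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-10)
  expect_equal(acos(sum(u * v)) * 180 / pi, 47.71, tolerance = 1e-10)

  scd <- displacement_scenario("divergent", k = 12, angle = 90)
  D1 <- scd$directions[, , 1]
  G <- crossprod(D1)
  expect_equal(G, diag(3), tolerance = 1e-10)  # pairwise 90 degrees
  scd2 <- displacement_scenario("divergent", k = 12, angle = 60)
  expect_equal(crossprod(scd2$directions[, , 2]),
               matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3), tolerance = 1e-10)
  expect_error(displacement_scenario("divergent", k = 12, angle = 150),
               "infeasible")
  expect_error(displacement_scenario("bogus", k = 12), "unknown scenario")

  scm <- displacement_scenario("magnitude_heterogeneous", k = 12,
                               base_magnitude = 0.1, ratios = c(1, 2, 3))
  expect_equal(scm$magnitudes[, 1], c(0.1, 0.2, 0.3))
})

test_that("simulation is reproducible and truth is consistent", {
  s1 <- quick_sim(n_per_cell = 3, seed = 77)
  s2 <- quick_sim(n_per_cell = 3, seed = 77)
  expect_identical(s1$dataset$coords, s2$dataset$coords)
  expect_identical(s1$dataset$factors, s2$dataset$factors)
  expect_equal(s1$truth$between_species_angle, 47.71, tolerance = 1e-10)
  expect_true(all(s1$truth$magnitudes == 0.05))
  expect_true(all(s1$truth$angles[upper.tri(s1$truth$angles[, , 1])] == 0))
  s3 <- quick_sim(n_per_cell = 3, seed = 78)
  expect_false(identical(s1$dataset$coords, s3$dataset$coords))
})

test_that("nuisance transforms do not change shape variables", {
  base <- sim_spec(n_per_cell = 4, seed = 21, nuisance = FALSE)
  with_n <- sim_spec(n_per_cell = 4, seed = 21, nuisance = TRUE)
  Y0 <- separate_subset_shape(simulate_shapes(base)$dataset)
  Y1 <- separate_subset_shape(simulate_shapes(with_n)$dataset)
  expect_lt(max(abs(unclass(Y0) - unclass(Y1))), 1e-8)
})

test_that("noise-free simulations are recovered exactly downstream", {
  spec <- sim_spec(n_per_cell = 3, noise_sd = 0, nuisance = FALSE, seed = 31)
  sim <- simulate_shapes(spec)
  Y <- separate_subset_shape(sim$dataset)
  ev <- evolution_vectors(ls_means(shape_model(Y, sim$dataset$factors)))
  expect_lt(max(abs(ev$magnitude - 0.05)), 1e-8)
  expect_lt(abs(between_species_angle(ev) - 47.71), 1e-6)
  pw <- pairwise_vector_stats(ev)
  expect_lt(max(pw$theta), 1e-5)
  expect_lt(max(pw$MD), 1e-8)
})

test_that("the default design mirrors the study constants", {
  spec <- default_study_design(seed = 3)
  expect_equal(spec$k, 12L)
  expect_equal(length(spec$transects), 3L)
  expect_equal(spec$nperm, 9999L)
  expect_equal(4 * length(spec$transects) * spec$n_per_cell, 336L)
  expect_equal(spec$between_angle, 47.71)
  sim <- simulate_shapes(spec)
  expect_equal(sim$dataset$n, 336L)
  expect_equal(ncol(separate_subset_shape(sim$dataset)), 18L)
})

test_that("over-large displacements warn about tangent linearity", {
  expect_warning(sim_spec(base_magnitude = 0.3), "0.2")
  expect_error(sim_spec(base_magnitude = -1), "nonnegative")
  expect_error(sim_spec(n_per_cell = 1), "n_per_cell")
})
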