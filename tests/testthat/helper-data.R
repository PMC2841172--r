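# fixtures built in code

tri_ref <- function() matrix(c(0, 1, 0, 0, 0, 1), 3, 2)

rand_config <- function(k, seed) {
  set.seed(seed)
  matrix(rnorm(2 * k), k, 2)
}

# apply a random similarity transform (rotation/translation/scale)
similarity_jitter <- function(x, seed) {
  set.seed(seed)
  th <- runif(1, -pi, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sc <- exp(runif(1, -1, 1))
  tr <- runif(2, -3, 3)
  sweep(sc * (x %*% R), 2, -tr)
}

quick_sim <- function(n_per_cell = 5, seed = 1, ...) {
  simulate_shapes(sim_spec(n_per_cell = n_per_cell, seed = seed, ...))
}

# minimal TPS text for io tests
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tps")
  writeLines(lines, f)
  f
}
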