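# synthetic landmark-data generator with known factorial truth

#' Deterministic head-like template configuration
#'
#' Places k landmarks on two nested arcs (an elongate outer outline and an
#' inner arc, loosely evoking a cranium in lateral view), centered with
#' unit centroid size.  Deterministic in k.
#'
#' @param k number of landmarks (>= 4; default 12).
#' @return a k x 2 configuration with unit centroid size.
#' @export
make_template <- function(k = 12L) {
  if (k < 4L) stop("template needs k >= 4 landmarks", call. = FALSE)
  n_out <- ceiling(k / 2)
  n_in <- k - n_out
  ang_out <- seq(-0.25, pi + 0.2, length.out = n_out)
  outer <- cbind(1.25 * cos(ang_out), sin(ang_out))
  ang_in <- seq(0.15, pi - 0.05, length.out = n_in)
  inner <- cbind(0.62 * cos(ang_in) + 0.08, 0.5 * sin(ang_in) - 0.15)
  center_scale(rbind(outer, inner))
}

#' Displacement-vector geometry for a simulation scenario
#'
#' Builds per species x transect displacement directions (unit vectors in
#' the 2k - 4 dimensional tangent coefficient space) and magnitudes for
#' the named scenario:
#' \describe{
#'   \item{null}{all magnitudes 0 (no character displacement).}
#'   \item{parallel}{within each species all transects share one direction
#'     and magnitude; the two species' directions are separated by
#'     `between_angle` degrees (default 47.71).}
#'   \item{divergent}{within-species directions pairwise `angle` degrees
#'     apart (constructed from the equi-correlated Gram matrix); the two
#'     species occupy orthogonal subspaces.}
#'   \item{magnitude_heterogeneous}{parallel directions, per-transect
#'     magnitudes scaled by `ratios`.}
#' }
#'
#' @param name scenario name.
#' @param k landmark count (sets the tangent dimension 2k - 4).
#' @param base_magnitude common displacement magnitude in Procrustes units.
#' @param n_transects number of transects (default 3).
#' @param between_angle between-species angle in degrees (parallel and
#'   magnitude_heterogeneous scenarios).
#' @param angle within-species pairwise angle in degrees (divergent).
#' @param ratios per-transect magnitude ratios (magnitude_heterogeneous).
#' @return list with `directions` (q x n_transects x 2 array) and
#'   `magnitudes` (n_transects x 2 matrix).
#' @export
displacement_scenario <- function(name, k = 12L, base_magnitude = 0.05,
                                  n_transects = 3L, between_angle = 47.71,
                                  angle = 90, ratios = NULL) {
  q <- 2L * k - 4L
  ax <- function(j) { v <- numeric(q); v[j] <- 1; v }
  dirs <- array(0, dim = c(q, n_transects, 2L))
  mags <- matrix(base_magnitude, n_transects, 2L)
  if (name == "null") {
    mags[] <- 0
    for (s in 1:2) for (t in seq_len(n_transects)) dirs[, t, s] <- ax(2)
  } else if (name %in% c("parallel", "magnitude_heterogeneous")) {
    if (q < 3L) stop("tangent dimension too small for this scenario",
                     call. = FALSE)
    a <- between_angle * pi / 180
    u1 <- ax(2)
    u2 <- cos(a) * ax(2) + sin(a) * ax(3)
    for (t in seq_len(n_transects)) { dirs[, t, 1] <- u1; dirs[, t, 2] <- u2 }
    if (name == "magnitude_heterogeneous") {
      if (is.null(ratios)) ratios <- seq(0.5, 1.5, length.out = n_transects)
      if (length(ratios) != n_transects)
        stop("ratios must have one entry per transect", call. = FALSE)
      mags <- base_magnitude * cbind(ratios, ratios)
    }
  } else if (name == "divergent") {
    ct <- cos(angle * pi / 180)
    if (ct < -1 / (n_transects - 1) + 1e-12)
      stop("infeasible pairwise angle set: ", angle, " degrees for ",
           n_transects, " directions", call. = FALSE)
    if (q < 1L + 2L * n_transects)
      stop("tangent dimension ", q, " too small for ", n_transects,
           " divergent directions per species", call. = FALSE)
    G <- matrix(ct, n_transects, n_transects); diag(G) <- 1
    eG <- eigen(G, symmetric = TRUE)
    M <- eG$vectors %*% diag(sqrt(pmax(eG$values, 0)), n_transects) %*%
      t(eG$vectors)
    for (s in 1:2) {
      block <- 2L + (s - 1L) * n_transects
      for (t in seq_len(n_transects))
        dirs[block:(block + n_transects - 1L), t, s] <- M[, t]
    }
  } else {
    stop("unknown scenario '", name, "'", call. = FALSE)
  }
  list(directions = dirs, magnitudes = mags)
}

#' Specify a factorial landmark simulation
#'
#' Describes a 2 species x 2 locality types x `transects` factorial design
#' on landmark data: for each species the allopatric mean is the template
#' displaced by half the species offset (the two species sit symmetrically
#' about the template), and each sympatric mean adds the scenario's
#' displacement vector for that species and transect.  All displacements
#' live in the template's tangent space; cell means are mapped back to
#' configuration space along the unit sphere (sqrt(1 - |t|^2) * template +
#' basis %*% t), which keeps tangent-space magnitudes exact.  The per-cell
#' mean displacements are centered on zero so that, for noise-free
#' balanced data, the Procrustes consensus coincides with the template and
#' the generating vectors are recovered exactly.
#'
#' @param k landmarks (default 12).
#' @param n_per_cell specimens per species x locality x transect cell
#'   (>= 2).
#' @param transects transect level names.
#' @param species the two species names.
#' @param scenario scenario name, see [displacement_scenario()].
#' @param base_magnitude displacement magnitude in Procrustes (tangent
#'   radian) units; a warning is issued above 0.2, where the small-
#'   displacement tangent approximation degrades.
#' @param between_angle between-species angle in degrees.
#' @param within_angle within-species pairwise angle (divergent scenario).
#' @param ratios magnitude ratios (magnitude_heterogeneous scenario).
#' @param species_offset_magnitude tangent distance between the two
#'   species' allopatric means.
#' @param noise_sd isotropic landmark-coordinate noise standard deviation;
#'   the default `base_magnitude / sqrt(2k - 4)` makes the per-specimen
#'   shape standard deviation comparable to the displacement magnitude.
#' @param nuisance logical: apply random per-specimen rotation,
#'   translation and scaling (removed again by GPA)?
#' @param sex_effect_magnitude tangent magnitude of a fixed male/female
#'   shape difference (0 = monomorphic).
#' @param partition optional [landmark_partition()] carried into the
#'   dataset.
#' @param nperm default permutation count recorded for downstream tests.
#' @param seed master seed; per-cell RNG streams are derived from it so
#'   changing one cell's n leaves the others untouched.
#' @return an object of class `sim_spec`.
#' @seealso [simulate_shapes()], [default_study_design()]
#' @export
sim_spec <- function(k = 12L, n_per_cell = 10L,
                     transects = c("HR", "KP", "TC"),
                     species = c("jordani", "teyahalee"),
                     scenario = "parallel",
                     base_magnitude = 0.05,
                     between_angle = 47.71,
                     within_angle = 90,
                     ratios = NULL,
                     species_offset_magnitude = 0.1,
                     noise_sd = NULL,
                     nuisance = FALSE,
                     sex_effect_magnitude = 0,
                     partition = NULL,
                     nperm = 999L,
                     seed = 1L) {
  if (n_per_cell < 2L) stop("n_per_cell must be >= 2", call. = FALSE)
  if (base_magnitude < 0 || species_offset_magnitude < 0)
    stop("magnitudes must be nonnegative", call. = FALSE)
  if (base_magnitude > 0.2)
    warning("displacement magnitude > 0.2 Procrustes units: tangent-space ",
            "linearity is questionable", call. = FALSE)
  template <- make_template(k)
  q <- 2L * k - 4L
  noise_sd <- noise_sd %||% (base_magnitude / sqrt(q))
  geom <- displacement_scenario(scenario, k = k,
                                base_magnitude = base_magnitude,
                                n_transects = length(transects),
                                between_angle = between_angle,
                                angle = within_angle, ratios = ratios)
  structure(list(k = k, template = template, n_per_cell = as.integer(n_per_cell),
                 transects = transects, species = species,
                 scenario = scenario, base_magnitude = base_magnitude,
                 between_angle = between_angle, within_angle = within_angle,
                 directions = geom$directions, magnitudes = geom$magnitudes,
                 species_offset_magnitude = species_offset_magnitude,
                 noise_sd = noise_sd, nuisance = isTRUE(nuisance),
                 sex_effect_magnitude = sex_effect_magnitude,
                 partition = partition, nperm = as.integer(nperm),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Landmark simulation spec:", x$scenario, "scenario\n")
  cat("  k =", x$k, "; 2 species x 2 locality types x",
      length(x$transects), "transects x n =", x$n_per_cell,
      "(total", 4 * length(x$transects) * x$n_per_cell, "specimens)\n")
  cat("  displacement magnitude", format(x$base_magnitude),
      "; noise sd", format(x$noise_sd, digits = 4),
      "; nuisance", x$nuisance, "\n")
  invisible(x)
}

#' The study design mirrored by the default simulation
#'
#' A `sim_spec` reproducing the source design's constants: 12 landmarks,
#' 3 transects (HR, KP, TC), 2 species, 336 specimens in total (28 per
#' cell), a parallel scenario with a 47.71-degree between-species angle,
#' a skull (1-7) / jaw (7-12) partition yielding 18 shape variables, sex
#' dimorphism, per-specimen nuisance transforms, and 9,999 permutations
#' for downstream tests.
#'
#' @param seed master seed (default 1).
#' @return a `sim_spec`.
#' @export
default_study_design <- function(seed = 1L) {
  sim_spec(k = 12L, n_per_cell = 28L, transects = c("HR", "KP", "TC"),
           species = c("jordani", "teyahalee"), scenario = "parallel",
           base_magnitude = 0.05, between_angle = 47.71,
           species_offset_magnitude = 0.1, nuisance = TRUE,
           sex_effect_magnitude = 0.04,
           partition = landmark_partition(skull = 1:7, jaw = 7:12),
           nperm = 9999L, seed = seed)
}

# per-cell tangent mean displacements (q x ncells), centered so the design
# mean displacement is zero; column order matches expand.grid(species,
# locality, transect) below
sim_cell_tau <- function(spec) {
  q <- 2L * spec$k - 4L
  nt <- length(spec$transects)
  cells <- expand.grid(species = seq_len(2L), locality = c("allopatric", "sympatric"),
                       transect = seq_len(nt), stringsAsFactors = FALSE)
  off <- numeric(q); off[1] <- 1
  tau <- matrix(0, q, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- cells$species[i]; t <- cells$transect[i]
    v <- (if (s == 1L) 0.5 else -0.5) * spec$species_offset_magnitude * off
    if (cells$locality[i] == "sympatric")
      v <- v + spec$magnitudes[t, s] * spec$directions[, t, s]
    tau[, i] <- v
  }
  tau <- tau - rowMeans(tau)
  list(cells = cells, tau = tau)
}

#' Simulate a factorial landmark dataset with known truth
#'
#' Generates specimens around the per-cell mean shapes implied by a
#' [sim_spec()]: isotropic Gaussian landmark noise, an optional fixed sex
#' effect (half of each cell male, half female, displaced symmetrically in
#' tangent space), and optional per-specimen nuisance similarity
#' transforms (rotation, translation, scaling), applied last.  Fully
#' reproducible under the specification's master seed; each cell draws from its own
#' derived RNG stream.
#'
#' @param spec a `sim_spec`.
#' @return a list with `dataset` (a [assemble_dataset()] result) and
#'   `truth` (class `sim_truth`: per-cell mean configurations, true vector
#'   magnitudes, within-species pairwise angles, and the true
#'   between-species angle).
#' @export
simulate_shapes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  k <- spec$k
  q <- 2L * k - 4L
  B <- tangent_basis(spec$template)
  ct <- sim_cell_tau(spec)
  nc <- nrow(ct$cells)
  if (any(colSums(ct$tau^2) >= 1))
    stop("tangent displacements too large to map back to configurations",
         call. = FALSE)
  mean_configs <- vector("list", nc)
  for (i in seq_len(nc)) {
    tau <- ct$tau[, i]
    mean_configs[[i]] <- sqrt(1 - sum(tau^2)) * spec$template +
      unvec_config(B %*% tau, k)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nc)
  nuis_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  sex_dir <- B[, q]  # last basis column, distinct from scenario axes
  n <- spec$n_per_cell
  configs <- list(); fac <- list()
  for (i in seq_len(nc)) {
    set.seed(cell_seeds[i])
    sp <- spec$species[ct$cells$species[i]]
    loc <- ct$cells$locality[i]
    tr <- spec$transects[ct$cells$transect[i]]
    sex <- rep(c("male", "female"), length.out = n)
    for (j in seq_len(n)) {
      m <- mean_configs[[i]]
      if (spec$sex_effect_magnitude > 0) {
        sgn <- if (sex[j] == "male") 0.5 else -0.5
        m <- m + unvec_config(sgn * spec$sex_effect_magnitude * sex_dir, k)
      }
      cfg <- m + matrix(stats::rnorm(2L * k, sd = spec$noise_sd), k, 2L)
      id <- sprintf("%s_%s_%s_%02d", sp, substr(loc, 1, 4), tr, j)
      configs[[id]] <- cfg
      fac[[id]] <- data.frame(specimen_id = id, species = sp, locality = loc,
                              transect = tr, sex = sex[j],
                              stringsAsFactors = FALSE)
    }
  }
  if (spec$nuisance) {
    set.seed(nuis_seed)
    for (id in names(configs)) {
      th <- stats::runif(1, -pi, pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sc <- exp(stats::runif(1, log(0.5), log(2)))
      tr2 <- stats::runif(2, -2, 2)
      configs[[id]] <- sweep(sc * (configs[[id]] %*% R), 2, -tr2)
    }
  }
  factors <- do.call(rbind, fac)
  rownames(factors) <- NULL
  dataset <- suppressWarnings(suppressMessages(
    assemble_dataset(configs, factors, partition = spec$partition)))
  truth <- sim_truth(spec, ct, mean_configs)
  list(dataset = dataset, truth = truth, spec = spec)
}

sim_truth <- function(spec, ct, mean_configs) {
  nt <- length(spec$transects)
  mags <- matrix(spec$magnitudes, nt, 2,
                 dimnames = list(spec$transects, spec$species))
  ang <- array(NA_real_, dim = c(nt, nt, 2L),
               dimnames = list(spec$transects, spec$transects, spec$species))
  for (s in 1:2) for (i in seq_len(nt)) for (j in seq_len(nt))
    ang[i, j, s] <- if (mags[i, s] > 0 && mags[j, s] > 0)
      angle_deg(spec$directions[, i, s], spec$directions[, j, s]) else NA_real_
  mean_vec <- sapply(1:2, function(s)
    rowMeans(sapply(seq_len(nt), function(t)
      spec$magnitudes[t, s] * spec$directions[, t, s])))
  between <- angle_deg(mean_vec[, 1], mean_vec[, 2])
  names(mean_configs) <- sprintf("%s.%s.%s",
                                 spec$species[ct$cells$species],
                                 ct$cells$locality,
                                 spec$transects[ct$cells$transect])
  structure(list(scenario = spec$scenario, cell_means = mean_configs,
                 magnitudes = mags, angles = ang,
                 between_species_angle = between),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth (", x$scenario, " scenario)\n", sep = "")
  cat("  vector magnitudes:\n")
  print(round(x$magnitudes, 5))
  cat("  between-species angle:", round(x$between_species_angle, 3),
      "degrees\n")
  invisible(x)
}

#' Write a simulated dataset to disk (TPS + CSV + truth JSON)
#'
#' @param sim output of [simulate_shapes()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(sim$dataset, file.path(dir, "landmarks.tps"))
  write_factors(sim$dataset$factors, file.path(dir, "factors.csv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(scenario = tr$scenario,
         magnitudes = as.data.frame(tr$magnitudes),
         between_species_angle = tr$between_species_angle),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$spec))
    jsonlite::write_json(
      list(n_specimens = sim$dataset$n, n_landmarks = sim$spec$k,
           n_transects = length(sim$spec$transects),
           n_per_cell = sim$spec$n_per_cell, nperm = sim$spec$nperm,
           scenario = sim$spec$scenario, seed = sim$spec$seed),
      file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
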