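# figures and the end-to-end pipeline

#' Principal-component trajectory plot
#'
#' Specimens as small points on the first two PCs, least-squares cell
#' means as large symbols, and an allopatry-to-sympatry arrow per species
#' x transect (line type distinguishes transects).  All plotted
#' coordinates are returned invisibly so tests and callers can assert on
#' geometry rather than pixels.
#'
#' @param pca a [shape_pca()] of the same shape matrix the model was fit
#'   to.
#' @param lsm the [ls_means()] matrix.
#' @param vectors an [evolution_vectors()] object (may have zero rows for
#'   a points-only plot).
#' @param factors specimen factor table (colors species).
#' @param file optional PNG path; when given the plot is rendered there.
#' @return invisibly, a list with `points`, `ls_scores` and `arrows`
#'   (x0, y0, x1, y1, species, transect).
#' @export
trajectory_plot <- function(pca, lsm, vectors = NULL, factors = NULL,
                            file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  sc <- pca$scores[, 1:2, drop = FALSE]
  ls2 <- sweep(unclass(lsm), 2, pca$center) %*% pca$loadings[, 1:2]
  cells <- attr(lsm, "cells")
  arrows_df <- NULL
  if (!is.null(vectors) && length(vectors$magnitude)) {
    rows <- lapply(seq_along(vectors$species), function(i) {
      a <- which(cells$species == vectors$species[i] &
                   cells$transect == vectors$transect[i] &
                   cells$locality == "allopatric")
      s <- which(cells$species == vectors$species[i] &
                   cells$transect == vectors$transect[i] &
                   cells$locality == "sympatric")
      data.frame(x0 = ls2[a, 1], y0 = ls2[a, 2], x1 = ls2[s, 1],
                 y1 = ls2[s, 2], species = vectors$species[i],
                 transect = vectors$transect[i], stringsAsFactors = FALSE)
    })
    arrows_df <- do.call(rbind, rows)
  }
  spcol <- if (!is.null(factors))
    c("grey40", "grey75")[as.integer(factor(factors$species))] else "grey60"
  plot(sc, pch = 16, cex = 0.6, col = spcol, asp = 1,
       xlab = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2]), ...)
  points(ls2, pch = 21, bg = ifelse(cells$locality == "sympatric",
                                    "black", "white"), cex = 1.4)
  if (!is.null(arrows_df)) {
    lty <- as.integer(factor(arrows_df$transect))
    arrows(arrows_df$x0, arrows_df$y0, arrows_df$x1, arrows_df$y1,
           length = 0.08, lty = lty, lwd = 1.6)
  }
  invisible(list(points = sc, ls_scores = ls2, arrows = arrows_df))
}

#' Thin-plate-spline deformation grids for fitted cell means
#'
#' Renders, per anatomical subset, the deformation of the consensus into
#' each species' sympatric mean shape, plus a single grid for the pooled
#' allopatric mean, mirroring the standard presentation of character-
#' displacement results.  Displacements can be exaggerated for legibility.
#'
#' @param analysis a [displacement_analysis()] object.
#' @param exaggeration multiplier applied to the deviation of each target
#'   from the consensus (default 1).
#' @param resolution grid cells per axis.
#' @param file optional PNG path.
#' @return invisibly, a list of `tps_grid` objects named
#'   `<subset>.<label>`, each carrying its bending energy.
#' @export
deformation_report <- function(analysis, exaggeration = 1, resolution = 24L,
                               file = NULL) {
  lsm <- analysis$ls_means
  cells <- attr(lsm, "cells")
  sm <- analysis$shapes
  targets <- list(allopatric = colMeans(unclass(lsm)[cells$locality ==
                                                       "allopatric", , drop = FALSE]))
  for (sp in unique(cells$species))
    targets[[paste0("sympatric.", sp)]] <-
      colMeans(unclass(lsm)[cells$locality == "sympatric" &
                              cells$species == sp, , drop = FALSE])
  grids <- list()
  for (lab in names(targets)) {
    cfgs <- shape_from_scores(sm, targets[[lab]])
    for (subset in names(cfgs)) {
      ref <- attr(sm, "bases")[[subset]]$consensus
      tgt <- ref + exaggeration * (cfgs[[subset]] - ref)
      grids[[paste(subset, lab, sep = ".")]] <-
        tps_grid(ref, tgt, resolution = resolution)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 300 * length(grids), height = 320)
    on.exit(grDevices::dev.off())
    op <- par(mfrow = c(1, length(grids)), mar = c(1, 1, 2, 1))
    on.exit(par(op), add = TRUE)
    for (lab in names(grids))
      plot(grids[[lab]], main = sprintf("%s (BE %.3g)", lab,
                                        grids[[lab]]$bending_energy))
  }
  invisible(grids)
}

default_pipeline_config <- function() {
  list(command = "all", out_dir = "morphodisp_run", seed = 1L,
       n_per_cell = 10L, scenario = "parallel", base_magnitude = 0.05,
       between_angle = 47.71, noise_sd = NULL, nuisance = TRUE,
       sex_effect_magnitude = 0, nperm = 199L, alpha = 0.05,
       partition = list(skull = 1:7, jaw = 7:12), k = 12L,
       landmarks = NULL, factors = NULL)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  for (nm in names(config)) cfg[nm] <- config[nm]  # preserves NULL overrides
  cfg
}

#' Run the simulate / analyze / report pipeline
#'
#' `simulate` writes TPS landmarks, a factor CSV and a truth JSON into the
#' run directory; `analyze` reads them back through the standard readers,
#' runs [displacement_analysis()] and writes the MANOVA table, the
#' pairwise vector comparisons, the variance summaries and a run log
#' (package version, seed, permutation count, config hash); `report`
#' renders the PC trajectory plot and deformation grids; `all` chains the
#' three.  Identical config and seed give byte-identical tables.
#'
#' @param config a named list or path to a JSON config file; unspecified
#'   entries fall back to defaults (see `default_pipeline_config` in the
#'   source).
#' @param command one of `"simulate"`, `"analyze"`, `"report"`, `"all"`.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config = list(), command = c("all", "simulate",
                                                      "analyze", "report")) {
  command <- match.arg(command)
  config_path <- if (is.character(config)) config else NULL
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (command %in% c("simulate", "all")) {
    spec <- sim_spec(k = cfg$k, n_per_cell = cfg$n_per_cell,
                     scenario = cfg$scenario,
                     base_magnitude = cfg$base_magnitude,
                     between_angle = cfg$between_angle,
                     noise_sd = cfg$noise_sd, nuisance = isTRUE(cfg$nuisance),
                     sex_effect_magnitude = cfg$sex_effect_magnitude,
                     partition = if (!is.null(cfg$partition))
                       landmark_partition(cfg$partition),
                     nperm = cfg$nperm, seed = cfg$seed)
    write_simulation(simulate_shapes(spec), cfg$out_dir)
    cfg$landmarks <- file.path(cfg$out_dir, "landmarks.tps")
    cfg$factors <- file.path(cfg$out_dir, "factors.csv")
  }
  ana <- NULL
  if (command %in% c("analyze", "report", "all")) {
    if (is.null(cfg$landmarks) || !file.exists(cfg$landmarks))
      stop("landmark file not found: ", cfg$landmarks %||% "<unset>",
           call. = FALSE)
    configs <- read_tps(cfg$landmarks)
    factors <- read_factors(cfg$factors)
    dataset <- assemble_dataset(configs, factors,
                                partition = if (!is.null(cfg$partition))
                                  landmark_partition(cfg$partition))
    ana <- displacement_analysis(dataset, nperm = cfg$nperm, seed = cfg$seed,
                                 alpha = cfg$alpha)
  }
  if (command %in% c("analyze", "all")) {
    utils::write.csv(ana$manova, file.path(cfg$out_dir, "manova_table.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$pairwise, file.path(cfg$out_dir, "pairwise_vectors.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(species = ana$vectors$species,
                                transect = ana$vectors$transect,
                                magnitude = ana$vectors$magnitude),
                     file.path(cfg$out_dir, "vector_magnitudes.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$variance, file.path(cfg$out_dir, "variance_summaries.csv"),
                     row.names = FALSE)
    sink(file.path(cfg$out_dir, "summary.txt"))
    print(summary(ana))
    sink()
    jsonlite::write_json(
      list(package = "morphodisp",
           version = as.character(utils::packageVersion("morphodisp")),
           r_version = R.version.string,
           seed = cfg$seed, nperm = cfg$nperm,
           n_specimens = nrow(ana$shapes),
           n_landmarks = cfg$k,
           n_transects = nlevels(factor(ana$factors$transect)),
           model = deparse(ana$formula),
           between_angle = ana$between$angle,
           between_P = ana$between$P,
           config_md5 = if (!is.null(config_path))
             unname(tools::md5sum(config_path)) else NA),
      file.path(cfg$out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  if (command %in% c("report", "all")) {
    pca <- shape_pca(ana$shapes)
    trajectory_plot(pca, ana$ls_means, ana$vectors, ana$factors,
                    file = file.path(cfg$out_dir, "trajectories.png"))
    deformation_report(ana, file = file.path(cfg$out_dir,
                                             "deformation_grids.png"))
  }
  invisible(cfg$out_dir)
}
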