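#' Define a landmark partition for separate-subset superimposition
#'
#' Articulated structures (e.g. skull and jaw) can be superimposed
#' independently so that variation in the articulation angle (gape) does not
#' contaminate shape.  A partition names groups of landmark indices
#' (1-based); groups may share landmarks (e.g. the jaw articulation point).
#'
#' @param ... named integer vectors of landmark indices, each of length >= 3.
#' @return an object of class `landmark_partition`.
#' @examples
#' landmark_partition(skull = 1:7, jaw = 7:12)
#' @export
landmark_partition <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) &&
      !is.null(names(groups[[1]])))
    groups <- groups[[1]]
  if (length(groups) == 0L || is.null(names(groups)) || any(names(groups) == ""))
    stop("partition groups must be named", call. = FALSE)
  for (nm in names(groups)) {
    idx <- as.integer(groups[[nm]])
    if (length(idx) < 3L)
      stop("partition group '", nm, "' has fewer than 3 landmarks", call. = FALSE)
    if (anyDuplicated(idx) || any(idx < 1L))
      stop("partition group '", nm, "' has invalid indices", call. = FALSE)
    groups[[nm]] <- idx
  }
  structure(groups, class = "landmark_partition")
}

#' Assemble landmark configurations and factors into an analysis dataset
#'
#' Joins a set of landmark configurations with a specimen factor table,
#' validating that the id sets match exactly.  Rows are ordered by specimen
#' id so assembly is invariant to the input row order.  Per-cell sample
#' sizes of the species x locality x transect design are tabulated; cells
#' with n < 2 raise a warning (they are unusable for model fitting).
#'
#' @param configs list of k x 2 matrices (named by specimen id), a
#'   k x 2 x n array, or the output of [read_tps()].
#' @param factors a factor data frame, e.g. from [read_factors()]; passed
#'   through [normalize_factors()].
#' @param partition optional [landmark_partition()] describing anatomical
#'   subsets for separate-subset superimposition.
#' @return an object of class `landmark_dataset`: a list with elements
#'   `coords` (k x 2 x n array), `ids`, `factors`, `partition`, `k`, `n`
#'   and `cell_counts`.
#' @export
assemble_dataset <- function(configs, factors, partition = NULL) {
  a <- as_config_array(configs)
  ids <- config_ids(a)
  if (anyDuplicated(ids))
    stop("duplicate specimen ids in landmark data: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  factors <- normalize_factors(as.data.frame(factors))
  only_lm <- setdiff(ids, factors$specimen_id)
  only_fac <- setdiff(factors$specimen_id, ids)
  if (length(only_lm) || length(only_fac))
    stop("specimen id mismatch between landmarks and factors;",
         if (length(only_lm)) paste0(" landmarks only: ",
                                     paste(only_lm, collapse = ", "), ";"),
         if (length(only_fac)) paste0(" factors only: ",
                                      paste(only_fac, collapse = ", ")),
         call. = FALSE)
  ord <- order(ids)
  a <- a[, , ord, drop = FALSE]
  ids <- ids[ord]
  dimnames(a) <- list(NULL, c("x", "y"), ids)
  factors <- factors[match(ids, factors$specimen_id), , drop = FALSE]
  rownames(factors) <- NULL
  k <- dim(a)[1]
  if (k < 3L) stop("need at least 3 landmarks", call. = FALSE)
  if (!all(is.finite(a))) stop("non-finite landmark coordinates", call. = FALSE)
  if (!is.null(partition)) {
    if (!inherits(partition, "landmark_partition"))
      partition <- landmark_partition(partition)
    bad <- unlist(partition)[unlist(partition) > k]
    if (length(bad))
      stop("partition indices exceed landmark count k = ", k, call. = FALSE)
  }
  cells <- table(species = factors$species, locality = factors$locality,
                 transect = factors$transect)
  if (any(cells == 0L))
    warning("empty design cell(s) present; interactions involving them are ",
            "inestimable", call. = FALSE)
  else if (any(cells < 2L))
    warning("design cell(s) with n < 2; model fitting needs n >= 2 per cell",
            call. = FALSE)
  n_unknown <- sum(factors$sex == "unknown")
  if (n_unknown > 0L)
    message(n_unknown, " specimen(s) with unknown sex")
  structure(list(coords = a, ids = ids, factors = factors,
                 partition = partition, k = k, n = length(ids),
                 cell_counts = cells),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", x$n, "specimens,", x$k, "landmarks (2-D)\n")
  cat("Design: ", nlevels(x$factors$species), " species x ",
      nlevels(x$factors$locality), " locality types x ",
      nlevels(x$factors$transect), " transects\n", sep = "")
  if (!is.null(x$partition))
    cat("Partition:", paste(sprintf("%s (%d)", names(x$partition),
                                    lengths(x$partition)), collapse = ", "), "\n")
  cat("Per-cell n: ", paste(range(x$cell_counts), collapse = "-"), "\n")
  invisible(x)
}
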