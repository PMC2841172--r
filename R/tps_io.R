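#' Read landmark configurations from a TPS file
#'
#' Parses the classic morphometrics interchange dialect: each record starts
#' with `LM=k`, followed by `k` lines of `x y` coordinates and optional
#' `ID=`, `SCALE=` (and ignored `IMAGE=`) key lines.  `SCALE=` multiplies the
#' record's coordinates; records without `ID=` are numbered by their ordinal
#' position in the file.
#'
#' @param path path to a TPS file.
#' @return A named list of k x 2 coordinate matrices, one per specimen.
#'   All records must share the same landmark count.
#' @seealso [write_tps()], [assemble_dataset()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  ids <- character()
  ks <- integer()
  i <- 1L
  n_lines <- length(lines)
  ordinal <- 0L
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("line ", i, ": expected 'LM=' record header, got '", ln, "'",
           call. = FALSE)
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 3L)
      stop("line ", i, ": malformed landmark count in '", ln, "'", call. = FALSE)
    ordinal <- ordinal + 1L
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    got <- 0L
    while (got < k) {
      if (i > n_lines)
        stop("record ", ordinal, ": file ended before ", k,
             " coordinate lines were read", call. = FALSE)
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      xy <- suppressWarnings(as.numeric(strsplit(ln, "[ \t,]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("line ", i, ": non-numeric coordinate line '", ln, "'", call. = FALSE)
      got <- got + 1L
      coords[got, ] <- xy
      i <- i + 1L
    }
    id <- as.character(ordinal)
    scale <- NA_real_
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) break
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- trimws(sub("^ID\\s*=", "", ln, ignore.case = TRUE))
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=", "", ln,
                                                 ignore.case = TRUE)))
        if (is.na(scale))
          stop("line ", i, ": malformed SCALE value", call. = FALSE)
      }
      # other KEY=VALUE lines (IMAGE=, ...) are ignored
      i <- i + 1L
    }
    if (!is.na(scale)) coords <- coords * scale
    if (!all(is.finite(coords)))
      stop("record ", ordinal, " ('", id, "'): non-finite coordinates",
           call. = FALSE)
    configs[[length(configs) + 1L]] <- coords
    ids <- c(ids, id)
    ks <- c(ks, k)
  }
  if (length(configs) == 0L) stop("no TPS records found in ", path, call. = FALSE)
  if (length(unique(ks)) > 1L)
    stop("inconsistent landmark counts across records: ",
         paste(sort(unique(ks)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate specimen ids in TPS file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(configs) <- ids
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written with 17 significant digits so a write-then-read
#' round trip reproduces them exactly.
#'
#' @param configs a landmark dataset, k x 2 x n array, or list of k x 2
#'   matrices.
#' @param path output file path.
#' @param ids optional character vector of specimen ids; defaults to the
#'   names carried by `configs`.
#' @export
write_tps <- function(configs, path, ids = NULL) {
  a <- as_config_array(configs)
  ids <- ids %||% config_ids(a)
  n <- dim(a)[3]
  k <- dim(a)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.17g %.17g", a[, 1, i], a[, 2, i]), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
  }
  invisible(path)
}
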