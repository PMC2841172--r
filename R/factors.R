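#' Default alias table for locality types
#'
#' Maps common spellings onto the two canonical locality levels,
#' `allopatric` and `sympatric`.  Matching is case-insensitive.
#'
#' @return a named list of character vectors.
#' @export
default_locality_aliases <- function() {
  list(allopatric = c("allopatric", "allopatry", "allo", "a"),
       sympatric  = c("sympatric", "sympatry", "sym", "symp", "s"))
}

normalize_locality <- function(x, aliases = default_locality_aliases()) {
  lev <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lev))
  for (canon in names(aliases))
    out[lev %in% tolower(c(canon, aliases[[canon]]))] <- canon
  if (anyNA(out))
    stop("locality values not recognized as allopatric/sympatric: ",
         paste(unique(lev[is.na(out)]), collapse = ", "), call. = FALSE)
  factor(out, levels = c("allopatric", "sympatric"))
}

normalize_sex <- function(x) {
  lev <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(lev))
  out[lev %in% c("m", "male")] <- "male"
  out[lev %in% c("f", "female")] <- "female"
  out[is.na(x) | lev == ""] <- "unknown"
  factor(out, levels = c("male", "female", "unknown"))
}

#' Normalize a specimen factor table
#'
#' Lower-cases and trims factor levels, maps locality spellings onto
#' `allopatric`/`sympatric` through an alias table, and recodes sex to
#' `male`/`female`/`unknown` (`unknown` is a first-class level so models can
#' drop or retain those specimens explicitly).
#'
#' @param x a data frame with columns `specimen_id`, `species`,
#'   `locality` (or `locality_type`), `transect`, and optionally `sex`.
#' @param locality_aliases alias table, see [default_locality_aliases()].
#' @return a data frame with normalized factor columns.
#' @export
normalize_factors <- function(x, locality_aliases = default_locality_aliases()) {
  names(x)[names(x) == "locality_type"] <- "locality"
  required <- c("specimen_id", "species", "locality", "transect")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$specimen_id <- as.character(x$specimen_id)
  if (anyDuplicated(x$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(x$specimen_id[duplicated(x$specimen_id)]), collapse = ", "),
         call. = FALSE)
  x$species <- factor(tolower(trimws(as.character(x$species))))
  x$locality <- normalize_locality(x$locality, locality_aliases)
  x$transect <- factor(trimws(as.character(x$transect)))
  x$sex <- if ("sex" %in% names(x)) normalize_sex(x$sex)
           else factor(rep("unknown", nrow(x)),
                       levels = c("male", "female", "unknown"))
  x[c("specimen_id", "species", "locality", "transect", "sex")]
}

#' Read a specimen factor table from delimited text
#'
#' @param path path to a CSV (or TSV, inferred from the extension) file with
#'   a header row containing `specimen_id`, `species`, `locality` (or
#'   `locality_type`), `transect` and optionally `sex`.
#' @param locality_aliases alias table mapping spellings onto
#'   allopatric/sympatric, see [default_locality_aliases()].
#' @return a normalized factor data frame (see [normalize_factors()]).
#' @export
read_factors <- function(path, locality_aliases = default_locality_aliases()) {
  if (!file.exists(path)) stop("factor file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  normalize_factors(tab, locality_aliases)
}

#' Write a factor table as CSV
#' @param factors a factor data frame.
#' @param path output path.
#' @export
write_factors <- function(factors, path) {
  utils::write.csv(factors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
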