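# Readers and writers for the plain-text formats the pipeline speaks:
# tab-separated abundance tables (metabolites in rows), two-column sample
# metadata, GMT metabolite-set libraries, and the YAML run configuration.

#' Construct a PathwayLibrary
#'
#' @param sets named list of character vectors (set name -> metabolite ids).
#' @param universe character vector of metabolite ids; every set is
#'   restricted to it.
#' @param warn_dropped warn when whole sets are dropped after restriction.
#' @return object of class `PathwayLibrary` with elements `sets`, `universe`,
#'   `n_dropped_members`.
#' @export
pathway_library <- function(sets, universe, warn_dropped = TRUE) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique", call. = FALSE)
  }
  universe <- as.character(universe)
  n_dropped <- 0L
  restricted <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s[s %in% universe]
    n_dropped <<- n_dropped + (length(s) - length(keep))
    keep
  })
  empty <- vapply(restricted, length, integer(1)) == 0L
  if (any(empty) && warn_dropped) {
    warning(sum(empty), " set(s) empty after restriction to the universe and dropped: ",
            paste(names(restricted)[empty], collapse = ", "), call. = FALSE)
  }
  if (n_dropped > 0 && warn_dropped) {
    message(n_dropped, " set member(s) outside the universe dropped")
  }
  structure(list(sets = restricted[!empty], universe = universe,
                 n_dropped_members = n_dropped),
            class = "PathwayLibrary")
}

#' @export
print.PathwayLibrary <- function(x, ...) {
  cat(sprintf("PathwayLibrary: %d sets over a universe of %d metabolites\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a tab-separated abundance table
#'
#' Expects a header row of sample ids, a first column of metabolite ids and
#' nonnegative numeric cells; blank cells become missing values for
#' [preprocess_matrix()] to handle. Ragged rows, duplicate ids and negative
#' values are format errors naming the offending cell.
#'
#' @param path file path.
#' @param metadata optional path to a two-column TSV (`sample_id`, `group`)
#'   assigning each sample to a condition group.
#' @return a [metabolite_matrix()].
#' @export
read_abundance_table <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2) stop("format error: need a header and at least one row", call. = FALSE)
  # field counts from tab counts so trailing blank cells are not dropped
  ntab <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  fields <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- ntab[i] + 1L
    f[is.na(f)] <- ""
    f
  })
  header <- fields[[1]]
  ncols <- length(header)
  sample_ids <- header[-1]
  body <- fields[-1]
  widths <- ntab[-1] + 1L
  if (any(widths != ncols)) {
    stop(sprintf("format error: ragged row at line %d (%d fields, expected %d)",
                 which(widths != ncols)[1] + 1L, widths[widths != ncols][1], ncols),
         call. = FALSE)
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  raw <- t(vapply(body, function(f) f[-1], character(ncols - 1L)))
  if (ncols == 2L) raw <- matrix(raw, ncol = 1L) # vapply drops 1-col to vector
  vals <- suppressWarnings(
    matrix(as.numeric(ifelse(trimws(raw) == "", NA, raw)), nrow(raw), ncol(raw))
  )
  bad <- which(trimws(raw) != "" & is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("format error: non-numeric value for metabolite '%s', sample '%s'",
                 ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  groups <- NULL
  if (!is.null(metadata)) groups <- read_sample_metadata(metadata)
  metabolite_matrix(vals, ids, sample_ids, groups = groups)
}

#' Write a MetaboliteMatrix as a tab-separated table
#'
#' Inverse of [read_abundance_table()]: values are printed with up to 12
#' significant digits so a write/read round trip reproduces the object.
#'
#' @param x a `MetaboliteMatrix`.
#' @param path output file path.
#' @param metadata optional path; when given, the sample-to-group table is
#'   written there as two-column TSV.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "MetaboliteMatrix"))
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 12, format = "g"))
  lines <- c(
    paste(c("metabolite_id", x$sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(x$values)), function(i) {
      paste(c(x$metabolite_ids[i], fmt(x$values[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  if (!is.null(metadata)) {
    if (is.null(x$groups)) stop("no group labels to write", call. = FALSE)
    writeLines(c("sample_id\tgroup",
                 paste(x$sample_ids, x$groups[x$sample_ids], sep = "\t")),
               metadata)
  }
  invisible(path)
}

#' Read a two-column sample metadata table
#'
#' @param path TSV with header `sample_id<TAB>group`.
#' @return named character vector sample id -> group.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("format error: metadata needs sample_id and group columns", call. = FALSE)
  if (anyDuplicated(df[[1]])) stop("format error: duplicate sample id in metadata", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Read a GMT metabolite-set library
#'
#' Standard GMT lines: set name, description, then tab-separated member ids.
#' Members outside the supplied universe are dropped (with a message giving
#' the count); sets empty after restriction are dropped with a warning.
#'
#' @param path GMT file path.
#' @param universe character vector of valid metabolite ids.
#' @return a [pathway_library()].
#' @export
read_gmt <- function(path, universe) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop(sprintf("format error: GMT line %d has fewer than 3 fields", which(short)[1]),
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("format error: duplicate set name '", nm[duplicated(nm)][1], "'", call. = FALSE)
  }
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  pathway_library(sets, universe)
}

#' Write a PathwayLibrary as GMT
#'
#' @param lib a `PathwayLibrary`.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path, descriptions = NULL) {
  stopifnot(inherits(lib, "PathwayLibrary"))
  lines <- vapply(names(lib$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, desc, lib$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
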