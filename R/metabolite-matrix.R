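#' Construct a MetaboliteMatrix
#'
#' The central data container: a nonnegative metabolite-by-sample relative
#' abundance matrix with unique metabolite and sample identifiers and an
#' optional assignment of samples to condition groups. Metabolites are rows,
#' samples are columns; transposed input is never guessed at.
#'
#' @param values numeric matrix, metabolites in rows, samples in columns.
#'   Missing values (`NA`) are allowed (handled by [preprocess_matrix()]);
#'   negative values are not.
#' @param metabolite_ids character vector of unique row identifiers. Defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique column identifiers. Defaults
#'   to `colnames(values)`.
#' @param groups optional named character vector mapping every sample id to a
#'   group name, or `NULL` when no grouping is known.
#' @return an object of class `MetaboliteMatrix`: a list with elements
#'   `values`, `metabolite_ids`, `sample_ids`, `groups`.
#' @examples
#' m <- metabolite_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("m1", "m2"), c("s1", "s2"))))
#' dim(m$values)
#' @export
metabolite_matrix <- function(values, metabolite_ids = rownames(values),
                              sample_ids = colnames(values), groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(metabolite_ids) || is.null(sample_ids)) {
    stop("metabolite and sample identifiers are required", call. = FALSE)
  }
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (length(metabolite_ids) != nrow(values)) {
    stop("length of `metabolite_ids` does not match nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of `sample_ids` does not match ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance at metabolite '%s', sample '%s'",
                 metabolite_ids[neg[1, 1]], sample_ids[neg[1, 2]]), call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    if (is.null(names(groups)) || !setequal(names(groups), sample_ids) ||
        length(groups) != length(sample_ids)) {
      stop("`groups` must name every sample id exactly once", call. = FALSE)
    }
    groups <- groups[sample_ids] # canonical order
  }
  dimnames(values) <- list(metabolite_ids, sample_ids)
  structure(
    list(values = values, metabolite_ids = metabolite_ids,
         sample_ids = sample_ids, groups = groups),
    class = "MetaboliteMatrix"
  )
}

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  cat(sprintf("MetaboliteMatrix: %d metabolites x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  }
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("missing values:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.MetaboliteMatrix <- function(x) dim(x$values)
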