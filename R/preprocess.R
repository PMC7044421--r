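#' Impute missing values and scale a metabolite matrix
#'
#' Prepares raw relative abundances for Frobenius-loss factorization.
#' Imputation rules: `half_min` replaces a metabolite's missing entries by
#' half its observed minimum across samples (the standard treatment of
#' below-detection-limit peaks); `drop` removes any metabolite with a missing
#' value. Scaling rules: `row_mean` divides each metabolite row by its mean
#' so no single high-abundance peak dominates the loss; `none` leaves values
#' untouched. Metabolites that end up all-missing or all-zero are removed
#' with a warning; the output has no missing values and no all-zero rows.
#'
#' @param x a [metabolite_matrix()].
#' @param impute `"half_min"` (default) or `"drop"`.
#' @param scale `"row_mean"` (default) or `"none"`.
#' @return a `MetaboliteMatrix` with the surviving metabolites.
#' @examples
#' m <- metabolite_matrix(matrix(c(2, NA, 4, 1, 2, 3), 2, 3, byrow = TRUE,
#'   dimnames = list(c("m1", "m2"), c("s1", "s2", "s3"))))
#' preprocess_matrix(m, scale = "none")$values["m1", ]
#' @export
preprocess_matrix <- function(x, impute = c("half_min", "drop"),
                              scale = c("row_mean", "none")) {
  stopifnot(inherits(x, "MetaboliteMatrix"))
  impute <- match.arg(impute)
  scale <- match.arg(scale)
  v <- x$values

  if (impute == "drop") {
    keep <- rowSums(is.na(v)) == 0L
    if (!all(keep)) {
      message(sum(!keep), " metabolite(s) with missing values dropped")
    }
    v <- v[keep, , drop = FALSE]
  } else {
    all_missing <- rowSums(!is.na(v)) == 0L
    if (any(all_missing)) {
      warning("metabolite(s) entirely missing removed: ",
              paste(rownames(v)[all_missing], collapse = ", "), call. = FALSE)
      v <- v[!all_missing, , drop = FALSE]
    }
    for (i in which(rowSums(is.na(v)) > 0L)) {
      obs_min <- min(v[i, ], na.rm = TRUE)
      v[i, is.na(v[i, ])] <- obs_min / 2
    }
  }

  zero <- rowMeans(v) == 0
  if (any(zero)) {
    warning("all-zero metabolite row(s) removed: ",
            paste(rownames(v)[zero], collapse = ", "), call. = FALSE)
    v <- v[!zero, , drop = FALSE]
  }
  if (nrow(v) == 0L) stop("no metabolites survive preprocessing", call. = FALSE)

  if (scale == "row_mean") {
    v <- v / rowMeans(v)
  }

  metabolite_matrix(v, rownames(v), x$sample_ids, groups = x$groups)
}
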