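# Two-group comparison statistics: per-metabolite t-tests with star codes,
# precursor-to-product percentage ratios, and named cofactor ratios
# (e.g. AMP/ATP, NAD+/NADH).

star_code <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", ""))))
}

# two-sided two-sample t-test; zero variance in both groups with equal means
# yields p = 1 by convention (message emitted by callers where relevant)
two_group_t <- function(a, b, test = c("student", "welch")) {
  test <- match.arg(test)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  degenerate = TRUE))
    }
    # zero variance but different means: infinitely strong evidence
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = (test == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Per-metabolite differential abundance between two groups
#'
#' Two-sided two-sample t-test for every metabolite (pooled-variance
#' Student's t by default, Welch optionally), with group means, SDs, fold
#' change (group A mean over group B mean) and the conventional star code
#' (* p < 0.05, ** p < 0.01, *** p < 0.001, **** p < 0.0001). No
#' across-metabolite correction is applied by default; `append_bh = TRUE`
#' adds Benjamini-Hochberg q-values as an extra column.
#'
#' @param x a [metabolite_matrix()] with group labels.
#' @param group_a,group_b group names; `group_a` is the fold-change
#'   numerator.
#' @param test `"student"` (default) or `"welch"`.
#' @param append_bh append a BH `q` column across metabolites.
#' @return object of class `DifferentialTable`: data.frame with one row per
#'   metabolite: `metabolite`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `fold_change`, `t`, `df`, `p`, `stars` (and `q` when requested).
#' @export
differential_abundance <- function(x, group_a, group_b,
                                   test = c("student", "welch"),
                                   append_bh = FALSE) {
  stopifnot(inherits(x, "MetaboliteMatrix"))
  test <- match.arg(test)
  if (is.null(x$groups)) stop("matrix has no group labels", call. = FALSE)
  ia <- which(x$groups == group_a)
  ib <- which(x$groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (any(is.na(x$values))) {
    stop("matrix contains missing values; run preprocess_matrix() first", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(x$values)), function(i) {
    a <- x$values[i, ia]; b <- x$values[i, ib]
    tt <- two_group_t(a, b, test)
    data.frame(metabolite = x$metabolite_ids[i],
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               fold_change = if (mean(b) > 0) mean(a) / mean(b) else NA_real_,
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- star_code(out$p)
  if (append_bh) out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "test") <- test
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

group_indices <- function(x, groups) {
  if (is.null(x$groups)) stop("matrix has no group labels", call. = FALSE)
  if (is.null(groups)) groups <- unique(x$groups)
  lapply(stats::setNames(groups, groups), function(g) which(x$groups == g))
}

metabolite_row <- function(x, id) {
  i <- match(id, x$metabolite_ids)
  if (is.na(i)) stop("metabolite id not found: ", id, call. = FALSE)
  x$values[i, ]
}

#' Precursor-to-product ratio analysis
#'
#' For every sample, expresses the product metabolite as a percentage of its
#' precursor (`100 * product / precursor`); reports per-group mean and SEM
#' of the percentages and a two-sided t-test for the group difference.
#'
#' @param x a [metabolite_matrix()] with group labels.
#' @param precursor,product metabolite ids; every precursor value must be
#'   positive.
#' @param groups character vector of group names: two groups for a
#'   between-group test, or one group for a summary only; defaults to the
#'   groups present.
#' @param test `"student"` (default) or `"welch"`.
#' @return object of class `RatioResult`: list with `precursor`, `product`,
#'   `per_sample` (percentages, named), `summary` (per-group data.frame with
#'   `mean`, `sem`, `n`), `t`, `df`, `p`, `dispersion = "sem"`.
#' @export
precursor_product_ratio <- function(x, precursor, product, groups = NULL,
                                    test = c("student", "welch")) {
  stopifnot(inherits(x, "MetaboliteMatrix"))
  test <- match.arg(test)
  pre <- metabolite_row(x, precursor)
  prod <- metabolite_row(x, product)
  bad <- which(is.na(pre) | pre <= 0)
  if (length(bad) > 0) {
    stop("non-positive precursor value in sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  pct <- 100 * prod / pre
  idx <- group_indices(x, groups)
  if (!length(idx) %in% 1:2) stop("one or two groups required", call. = FALSE)
  summ <- do.call(rbind, lapply(names(idx), function(g) {
    v <- pct[idx[[g]]]
    data.frame(group = g, mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               n = length(v), stringsAsFactors = FALSE)
  }))
  tt <- if (length(idx) == 2L) two_group_t(pct[idx[[1]]], pct[idx[[2]]], test) else
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  structure(
    list(precursor = precursor, product = product, per_sample = pct,
         summary = summ, t = tt$t, df = tt$df, p = tt$p, dispersion = "sem"),
    class = "RatioResult"
  )
}

#' Named metabolite ratio between two groups
#'
#' Per-sample ratio of two metabolites (e.g. AMP/ATP or NAD+/NADH) with
#' per-group mean and SD and a two-sided t-test on the per-sample ratios.
#'
#' @inheritParams precursor_product_ratio
#' @param numerator,denominator metabolite ids; every denominator value must
#'   be positive.
#' @return object of class `RatioResult` with `per_sample` ratios, per-group
#'   `summary` (`mean`, `sd`, `n`), `t`, `df`, `p`, `dispersion = "sd"`.
#' @export
metabolite_ratio <- function(x, numerator, denominator, groups = NULL,
                             test = c("student", "welch")) {
  stopifnot(inherits(x, "MetaboliteMatrix"))
  test <- match.arg(test)
  num <- metabolite_row(x, numerator)
  den <- metabolite_row(x, denominator)
  bad <- which(is.na(den) | den <= 0)
  if (length(bad) > 0) {
    stop("non-positive denominator value in sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  ratio <- num / den
  idx <- group_indices(x, groups)
  if (!length(idx) %in% 1:2) stop("one or two groups required", call. = FALSE)
  summ <- do.call(rbind, lapply(names(idx), function(g) {
    v <- ratio[idx[[g]]]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  tt <- if (length(idx) == 2L) two_group_t(ratio[idx[[1]]], ratio[idx[[2]]], test) else
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  structure(
    list(numerator = numerator, denominator = denominator, per_sample = ratio,
         summary = summ, t = tt$t, df = tt$df, p = tt$p, dispersion = "sd"),
    class = "RatioResult"
  )
}

#' @export
print.RatioResult <- function(x, ...) {
  lab <- if (!is.null(x$precursor)) {
    sprintf("%s -> %s (product as %% of precursor)", x$precursor, x$product)
  } else {
    sprintf("%s / %s", x$numerator, x$denominator)
  }
  cat("RatioResult:", lab, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("two-sided t-test: t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}
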