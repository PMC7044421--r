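# Nonnegative matrix factorization by Lee-Seung multiplicative updates for
# the Frobenius loss. This is the analytical core of the package: a sample's
# metabolite profile is modeled as a nonnegative mixture of column-stochastic
# "signatures" (appearance-probability profiles over metabolites), and the
# factorization rank is chosen by bootstrap stability.

MU_EPS <- 1e-12 # denominator guard in the multiplicative updates

as_values <- function(x) {
  if (inherits(x, "MetaboliteMatrix")) x$values else as.matrix(x)
}

check_nmf_input <- function(x) {
  if (any(is.na(x))) stop("degenerate input: matrix contains missing values", call. = FALSE)
  if (any(x < 0)) stop("degenerate input: matrix contains negative entries", call. = FALSE)
  zr <- rowSums(x) == 0
  zc <- colSums(x) == 0
  if (any(zr)) stop("degenerate input: all-zero row(s): ",
                    paste(which(zr), collapse = ", "), call. = FALSE)
  if (any(zc)) stop("degenerate input: all-zero column(s): ",
                    paste(which(zc), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Single NMF run by multiplicative updates
#'
#' Factorizes a nonnegative matrix `X ~ W H` (`W` M x k, `H` k x N) by
#' Lee-Seung multiplicative updates for the Frobenius loss:
#' `H <- H * (W'X) / (W'W H + eps)`, `W <- W * (X H') / (W H H' + eps)`
#' with `eps = 1e-12`. Factors are initialized uniform-random in (0, 1] from
#' `seed`; iteration stops when the relative decrease of the loss falls
#' below `tol` or after `max_iter` iterations. The loss is non-increasing
#' across iterations (a property of the updates); the full per-iteration
#' trace of the relative Frobenius error `||X - WH||_F / ||X||_F` is
#' returned for inspection.
#'
#' @param x nonnegative matrix or `MetaboliteMatrix` with at least one
#'   positive entry in every row and column.
#' @param k factorization rank, `1 <= k <= min(dim(x))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative loss-decrease stopping threshold.
#' @return list with `W`, `H`, `relative_error`, `loss_trace`, `iterations`,
#'   `converged`, `seed`.
#' @export
nmf_once <- function(x, k, seed = 1, max_iter = 2000, tol = 1e-6) {
  x <- as_values(x)
  check_nmf_input(x)
  m <- nrow(x); n <- ncol(x)
  k <- check_count(k, "k")
  if (k > min(m, n)) {
    stop("invalid parameter: rank k exceeds min(dim(x))", call. = FALSE)
  }
  max_iter <- check_count(max_iter, "max_iter")
  normx2 <- sum(x^2)

  init <- with_seed(seed, {
    list(W = matrix(1 - stats::runif(m * k), m, k),
         H = matrix(1 - stats::runif(k * n), k, n))
  })
  W <- init$W; H <- init$H

  # ||X - WH||^2 = ||X||^2 - 2 sum(W * XH') + sum(W'W * HH'); XH' depends
  # only on H, so after updating H then W both right-hand terms are current.
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    H <- H * crossprod(W, x) / (crossprod(W) %*% H + MU_EPS)
    XHt <- x %*% t(H)
    HHt <- tcrossprod(H)
    W <- W * XHt / (W %*% HHt + MU_EPS)
    loss2 <- max(normx2 - 2 * sum(W * XHt) + sum(crossprod(W) * HHt), 0)
    rel <- sqrt(loss2 / normx2)
    trace[iter] <- rel
    if (is.finite(prev) && (prev - rel) < tol * max(prev, MU_EPS)) {
      converged <- TRUE
      break
    }
    prev <- rel
  }
  rel_final <- sqrt(sum((x - W %*% H)^2)) / sqrt(normx2)
  list(W = W, H = H, relative_error = rel_final,
       loss_trace = trace[seq_len(iter)], iterations = iter,
       converged = converged, seed = as.integer(seed))
}

#' Normalize an NMF factorization into a SignatureSet
#'
#' Rescales each column of `W` to sum to one (an appearance-probability
#' profile over metabolites) and multiplies the corresponding row of `H` by
#' the same factor, so the product `W H` is algebraically unchanged.
#'
#' @param W,H factors from [nmf_once()].
#' @param relative_error optional relative Frobenius error to carry along.
#' @param seed optional seed to record.
#' @return object of class `SignatureSet`: `signatures` (M x K,
#'   column-stochastic), `weights` (K x N, nonnegative), `rank`,
#'   `reconstruction_error`, `per_signature_stability` (filled by
#'   [bootstrap_stability()]), `seed`.
#' @export
normalize_factorization <- function(W, H, relative_error = NA_real_, seed = NA_integer_) {
  W <- as.matrix(W); H <- as.matrix(H)
  if (ncol(W) != nrow(H)) stop("W and H have incompatible ranks", call. = FALSE)
  s <- colSums(W)
  if (any(s == 0)) {
    stop("degenerate signature: W column(s) ",
         paste(which(s == 0), collapse = ", "), " sum to zero", call. = FALSE)
  }
  sig <- sweep(W, 2, s, "/")
  wts <- H * s
  k <- ncol(sig)
  colnames(sig) <- rownames(wts) <- sprintf("S%d", seq_len(k))
  if (!is.null(rownames(W))) rownames(sig) <- rownames(W)
  if (!is.null(colnames(H))) colnames(wts) <- colnames(H)
  structure(
    list(signatures = sig, weights = wts, rank = k,
         reconstruction_error = relative_error,
         per_signature_stability = NULL, seed = seed),
    class = "SignatureSet"
  )
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d signatures over %d metabolites, %d samples\n",
              x$rank, nrow(x$signatures), ncol(x$weights)))
  cat(sprintf("relative reconstruction error: %.4g\n", x$reconstruction_error))
  if (!is.null(x$per_signature_stability)) {
    cat("per-signature stability:",
        paste(sprintf("%.3f", x$per_signature_stability), collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract signatures with multi-restart NMF
#'
#' Multiplicative updates converge to local optima, so the factorization is
#' repeated from `n_restarts` random initializations (seeds derived from
#' `seed`) and the solution with the lowest relative error is kept and
#' normalized into a [normalize_factorization()] `SignatureSet`.
#'
#' @inheritParams nmf_once
#' @param n_restarts number of random restarts.
#' @return a `SignatureSet`.
#' @export
extract_signatures <- function(x, k, seed = 1, n_restarts = 10,
                               max_iter = 2000, tol = 1e-6) {
  n_restarts <- check_count(n_restarts, "n_restarts")
  xm <- as_values(x)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_once(xm, k, seed = derive_seed(seed, "restart", r),
                    max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$relative_error < best$relative_error) best <- fit
  }
  out <- normalize_factorization(best$W, best$H,
                                 relative_error = best$relative_error,
                                 seed = as.integer(seed))
  out$loss_trace <- best$loss_trace
  out
}

# cache of permutation matrices (k! x k), one per k
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(v) {
    if (length(v) <= 1L) return(matrix(v, ncol = length(v)))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], gen(v[-i]), deparse.level = 0)
    }))
  }
  p <- gen(seq_len(k))
  .perm_cache[[key]] <- p
  p
}

cosine_similarity_matrix <- function(a, b) {
  an <- sweep(a, 2, pmax(sqrt(colSums(a^2)), MU_EPS), "/")
  bn <- sweep(b, 2, pmax(sqrt(colSums(b^2)), MU_EPS), "/")
  crossprod(an, bn)
}

#' Match signature columns between two factorizations
#'
#' Finds the one-to-one assignment of columns of `b` to columns of `a`
#' maximizing the total cosine similarity of matched pairs, by exhaustive
#' search over all K! permutations (K <= 10).
#'
#' @param a,b matrices with the same number of rows and columns (K each).
#' @return list with `permutation` (`a[, j]` is matched to
#'   `b[, permutation[j]]`) and `total_similarity`.
#' @export
match_signatures <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) {
    stop("invalid parameter: signature matrices must have identical dimensions",
         call. = FALSE)
  }
  k <- ncol(a)
  if (k > 10L) stop("invalid parameter: exhaustive matching supports K <= 10", call. = FALSE)
  cs <- cosine_similarity_matrix(a, b)
  perms <- all_permutations(k)
  scores <- matrix(cs[cbind(rep(seq_len(k), each = nrow(perms)), as.vector(perms))],
                   nrow(perms), k)
  totals <- rowSums(scores)
  best <- which.max(totals)
  list(permutation = as.integer(perms[best, ]), total_similarity = totals[best])
}

#' Bootstrap stability of signatures at a fixed rank
#'
#' Resamples samples (columns) with replacement `n_boot` times, refits the
#' factorization on each resample (seed `seed + b` for resample `b`), matches
#' each resampled solution's signatures to the reference full-data solution
#' by [match_signatures()], pools the matched signature vectors into K
#' clusters, and scores each cluster by its mean silhouette width under
#' cosine distance. Stable signatures reappear across resamples and give
#' silhouettes near 1; spurious ones scatter and drag the silhouette down.
#'
#' @inheritParams nmf_once
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param reference optional `SignatureSet` for the full data; computed via
#'   [extract_signatures()] when absent.
#' @param n_restarts restarts for the reference solution.
#' @param boot_restarts random restarts per bootstrap fit (best kept); more
#'   restarts separate genuine instability from local-optimum noise.
#' @return list with `per_signature_silhouette` (length K), `mean_stability`,
#'   `reference`, `n_boot`, and `pooled` (matrix of pooled matched
#'   signatures with cluster labels in `pooled_labels`).
#' @export
bootstrap_stability <- function(x, k, n_boot = 20, seed = 1, reference = NULL,
                                n_restarts = 10, boot_restarts = 3,
                                max_iter = 2000, tol = 1e-6) {
  xm <- as_values(x)
  check_nmf_input(xm)
  if (length(n_boot) != 1L || !is.numeric(n_boot) || n_boot < 2) {
    stop("invalid parameter: `n_boot` must be >= 2", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  n <- ncol(xm)
  if (is.null(reference)) {
    reference <- extract_signatures(xm, k, seed = seed, n_restarts = n_restarts,
                                    max_iter = max_iter, tol = tol)
  }
  ref_sig <- reference$signatures

  pooled <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, "resample", b), {
      cand <- sample.int(n, n, replace = TRUE)
      for (try in seq_len(100L)) {
        if (length(unique(cand)) >= 2L) break
        if (try == 100L) stop("bootstrap resampling failed to produce >= 2 distinct samples",
                              call. = FALSE)
        message("bootstrap resample ", b, " redrawn (fewer than 2 distinct samples)")
        cand <- sample.int(n, n, replace = TRUE)
      }
      cand
    })
    fit <- NULL
    for (r in seq_len(boot_restarts)) {
      cand <- nmf_once(xm[, idx, drop = FALSE], k,
                       seed = derive_seed(seed, "boot_nmf", b * 1000L + r),
                       max_iter = max_iter, tol = tol)
      if (is.null(fit) || cand$relative_error < fit$relative_error) fit <- cand
    }
    sig_b <- normalize_factorization(fit$W, fit$H)$signatures
    mt <- match_signatures(ref_sig, sig_b)
    pooled[[b]] <- sig_b[, mt$permutation, drop = FALSE]
  }

  vecs <- do.call(cbind, pooled)               # M x (K * n_boot)
  labels <- rep(seq_len(k), times = n_boot)
  sil_per_sig <- rep(NA_real_, k)
  if (k == 1L) {
    # single cluster: silhouette undefined; report mean pairwise cosine
    # similarity within the cluster instead (1 = perfectly reproducible)
    cs <- cosine_similarity_matrix(vecs, vecs)
    sil_per_sig <- mean(cs[upper.tri(cs)])
  } else {
    d <- stats::as.dist(1 - cosine_similarity_matrix(vecs, vecs))
    sil <- cluster::silhouette(labels, d)
    means <- tapply(sil[, "sil_width"], sil[, "cluster"], mean)
    sil_per_sig[as.integer(names(means))] <- as.numeric(means)
  }
  list(per_signature_silhouette = sil_per_sig,
       mean_stability = mean(sil_per_sig),
       reference = reference, n_boot = n_boot)
}

#' Select the factorization rank by bootstrap stability
#'
#' For every candidate rank, computes the mean bootstrap silhouette
#' stability and the mean reconstruction error of the reference solution,
#' then selects the largest rank whose mean stability reaches
#' `stability_threshold` (the "largest stable rank" heuristic used for
#' signature discovery). If no rank qualifies, the rank with the highest
#' mean stability is returned with a warning.
#'
#' @inheritParams bootstrap_stability
#' @param ranks integer vector of candidate ranks (or `c(min, max)` range
#'   given as a length-2 increasing vector).
#' @param stability_threshold minimum mean silhouette for a rank to qualify.
#' @return object of class `RankSelectionReport`: `candidate_ranks`,
#'   `mean_stability`, `mean_reconstruction_error`,
#'   `per_signature_stability` (list), `selected_rank`, `threshold`.
#' @export
select_rank <- function(x, ranks = 2:8, n_boot = 20, stability_threshold = 0.7,
                        seed = 1, n_restarts = 10, boot_restarts = 3,
                        max_iter = 2000, tol = 1e-6) {
  xm <- as_values(x)
  check_nmf_input(xm)
  if (length(ranks) == 0L) stop("invalid parameter: empty rank range", call. = FALSE)
  if (length(ranks) == 2L && ranks[2] > ranks[1] + 1L) ranks <- ranks[1]:ranks[2]
  ranks <- sort(unique(as.integer(ranks)))
  if (ranks[1] < 1L || ranks[length(ranks)] > min(dim(xm))) {
    stop("invalid parameter: ranks must lie within [1, min(dim(x))]", call. = FALSE)
  }
  stability <- err <- rep(NA_real_, length(ranks))
  per_sig <- vector("list", length(ranks))
  for (i in seq_along(ranks)) {
    k <- ranks[i]
    ref <- extract_signatures(xm, k, seed = derive_seed(seed, "rank_ref", k),
                              n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    bs <- bootstrap_stability(xm, k, n_boot = n_boot,
                              seed = derive_seed(seed, "rank_boot", k),
                              reference = ref, boot_restarts = boot_restarts,
                              max_iter = max_iter, tol = tol)
    stability[i] <- bs$mean_stability
    err[i] <- ref$reconstruction_error
    per_sig[[i]] <- bs$per_signature_silhouette
  }
  qualifying <- ranks[stability >= stability_threshold]
  if (length(qualifying) > 0) {
    selected <- max(qualifying)
  } else {
    selected <- ranks[which.max(stability)]
    warning("no candidate rank reached stability ", stability_threshold,
            "; returning the most stable rank ", selected, call. = FALSE)
  }
  structure(
    list(candidate_ranks = ranks, mean_stability = stability,
         mean_reconstruction_error = err, per_signature_stability = per_sig,
         selected_rank = selected, threshold = stability_threshold),
    class = "RankSelectionReport"
  )
}

#' @export
print.RankSelectionReport <- function(x, ...) {
  cat("Rank selection by bootstrap stability\n")
  df <- data.frame(rank = x$candidate_ranks,
                   mean_stability = round(x$mean_stability, 3),
                   mean_reconstruction_error = round(x$mean_reconstruction_error, 4))
  print(df, row.names = FALSE)
  cat("selected rank:", x$selected_rank,
      sprintf("(threshold %.2f)\n", x$threshold))
  invisible(x)
}
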