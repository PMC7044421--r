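# Hierarchical clustering of per-sample signature weight profiles, with
# cophenetic validation of the dendrogram, silhouette-based automatic cuts,
# and per-cluster signature centroids on the percent scale.

#' Pairwise distances between sample weight profiles
#'
#' Each sample is a column of the K x N weight matrix. `correlation` distance
#' is `1 - Pearson r` between weight vectors after normalizing each column to
#' sum 1 (so only profile shape matters); `cosine` is `1 - cosine similarity`;
#' `euclidean` is the ordinary distance on raw weights.
#'
#' @param weights K x N nonnegative matrix (or a `SignatureSet`).
#' @param metric `"correlation"` (default), `"cosine"` or `"euclidean"`.
#' @return a `stats::dist` over samples.
#' @export
weight_distances <- function(weights, metric = c("correlation", "cosine", "euclidean")) {
  metric <- match.arg(metric)
  w <- if (inherits(weights, "SignatureSet")) weights$weights else as.matrix(weights)
  ids <- colnames(w) %||% sprintf("sample%d", seq_len(ncol(w)))
  if (metric == "correlation") {
    cs <- colSums(w)
    if (any(cs == 0)) stop("sample(s) with all-zero weights: ",
                           paste(ids[cs == 0], collapse = ", "), call. = FALSE)
    wn <- sweep(w, 2, cs, "/")
    sds <- apply(wn, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant weight vector under correlation metric for sample(s): ",
           paste(ids[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(wn))
  } else if (metric == "cosine") {
    nrm <- sqrt(colSums(w^2))
    if (any(nrm == 0)) stop("sample(s) with all-zero weights: ",
                            paste(ids[nrm == 0], collapse = ", "), call. = FALSE)
    d <- stats::as.dist(1 - crossprod(sweep(w, 2, nrm, "/")))
  } else {
    d <- stats::dist(t(w))
  }
  attr(d, "Labels") <- ids
  d
}

#' Hierarchically cluster samples on their signature weights
#'
#' Agglomerative clustering of the pairwise [weight_distances()] with
#' `average` (UPGMA, default) or `complete` linkage.
#'
#' @inheritParams weight_distances
#' @param linkage `"average"` or `"complete"`.
#' @return object of class `SampleClustering`: `tree` (an `hclust`),
#'   `distances`, `metric`, `linkage`, `cophenetic_coefficient`.
#' @export
cluster_samples <- function(weights, metric = c("correlation", "cosine", "euclidean"),
                            linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  d <- weight_distances(weights, metric)
  n <- attr(d, "Size")
  if (n < 3L) stop("invalid parameter: clustering needs at least 3 samples", call. = FALSE)
  tree <- stats::hclust(d, method = linkage)
  cc <- tryCatch(cophenetic_correlation(tree, d), error = function(e) NA_real_)
  structure(
    list(tree = tree, distances = d, metric = metric, linkage = linkage,
         cophenetic_coefficient = cc),
    class = "SampleClustering"
  )
}

#' @export
print.SampleClustering <- function(x, ...) {
  cat(sprintf("SampleClustering: %d samples, %s distance, %s linkage\n",
              attr(x$distances, "Size"), x$metric, x$linkage))
  cat(sprintf("cophenetic correlation coefficient: %.3f\n", x$cophenetic_coefficient))
  invisible(x)
}

#' Cophenetic correlation coefficient of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height of the lowest common ancestor of
#' each pair). Values near 1 mean the hierarchy faithfully preserves the
#' distances.
#'
#' @param tree an `hclust` (or a `SampleClustering`).
#' @param distances the `dist` the tree was built from; taken from a
#'   `SampleClustering` automatically.
#' @return a single correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, distances = NULL) {
  if (inherits(tree, "SampleClustering")) {
    distances <- distances %||% tree$distances
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "hclust"), inherits(distances, "dist"))
  n <- attr(distances, "Size")
  if (n < 4L) stop("invalid parameter: need >= 4 samples (>= 6 distance pairs)", call. = FALSE)
  coph <- stats::cophenetic(tree)
  a <- as.vector(distances); b <- as.vector(coph)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance in the distance vectors", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Cut a sample dendrogram into clusters
#'
#' With a numeric `n_clusters`, cuts the tree into exactly that many
#' clusters. With `"auto"`, tries every cut from 2 to `min(8, N - 1)`
#' clusters and keeps the one maximizing the mean silhouette width under the
#' clustering distance, breaking ties toward fewer clusters.
#'
#' @param clustering a `SampleClustering` (or an `hclust` plus `distances`).
#' @param n_clusters integer >= 2, or `"auto"` (default).
#' @param distances required when `clustering` is a bare `hclust`.
#' @return integer vector of cluster labels named by sample id, with the
#'   chosen `k` and (for auto) the silhouette profile in attributes.
#' @export
cut_clusters <- function(clustering, n_clusters = "auto", distances = NULL) {
  if (inherits(clustering, "SampleClustering")) {
    tree <- clustering$tree
    distances <- distances %||% clustering$distances
  } else {
    tree <- clustering
    if (is.null(distances)) stop("`distances` required with a bare hclust", call. = FALSE)
  }
  n <- length(tree$order)
  if (identical(n_clusters, "auto")) {
    cands <- 2:min(8L, n - 1L)
    sils <- vapply(cands, function(c) {
      lab <- stats::cutree(tree, k = c)
      mean(cluster::silhouette(lab, distances)[, "sil_width"])
    }, numeric(1))
    best <- cands[which.max(sils)] # which.max takes the first (fewest clusters) on ties
    labels <- stats::cutree(tree, k = best)
    attr(labels, "k") <- best
    attr(labels, "silhouette_by_k") <- stats::setNames(sils, cands)
    return(labels)
  }
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L ||
      n_clusters != round(n_clusters) || n_clusters < 2 || n_clusters > n) {
    stop("invalid parameter: `n_clusters` must be 'auto' or an integer in [2, N]",
         call. = FALSE)
  }
  labels <- stats::cutree(tree, k = as.integer(n_clusters))
  attr(labels, "k") <- as.integer(n_clusters)
  labels
}

#' Per-cluster signature centroids in percent
#'
#' Normalizes every sample's weight vector to sum 100, then averages the
#' normalized vectors within each cluster: the centroid row gives the
#' relative contribution (%) of each signature in that cluster and sums
#' to 100.
#'
#' @param weights K x N weight matrix (or `SignatureSet`).
#' @param labels cluster labels named by (or ordered as) the samples.
#' @return clusters x signatures matrix of percentages.
#' @export
cluster_centroids <- function(weights, labels) {
  w <- if (inherits(weights, "SignatureSet")) weights$weights else as.matrix(weights)
  if (length(labels) != ncol(w)) stop("labels must cover every sample", call. = FALSE)
  ids <- colnames(w) %||% sprintf("sample%d", seq_len(ncol(w)))
  cs <- colSums(w)
  if (any(cs == 0)) stop("sample(s) with all-zero weights: ",
                         paste(ids[cs == 0], collapse = ", "), call. = FALSE)
  pct <- sweep(w, 2, cs / 100, "/") # each column sums to 100
  cl <- sort(unique(labels))
  cent <- t(vapply(cl, function(c) rowMeans(pct[, labels == c, drop = FALSE]),
                   numeric(nrow(w))))
  rownames(cent) <- paste0("cluster", cl)
  colnames(cent) <- rownames(w) %||% sprintf("S%d", seq_len(nrow(w)))
  cent
}

#' Write a sample dendrogram in Newick format
#'
#' Leaves are sample ids and branch lengths derive from the merge heights,
#' so the tree can be inspected in any phylogenetics viewer.
#'
#' @param clustering a `SampleClustering` or `hclust`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  tree <- if (inherits(clustering, "SampleClustering")) clustering$tree else clustering
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
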