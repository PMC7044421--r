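# helper: distances as an explicit dist with labels
as_labeled_dist <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  stats::as.dist(m)
}

test_that("duplicated samples merge first at height zero", {
  w <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(5, 1, 1), s4 = c(1, 6, 1))
  sc <- cluster_samples(w, metric = "euclidean")
  expect_equal(sc$tree$height[1], 0)
  first <- sc$tree$merge[1, ]
  expect_setequal(sc$tree$labels[-first], c("s1", "s2"))
})

test_that("average linkage on correlation distances matches a hand trace", {
  # profiles (1,2,3), (1,2,4), (3,2,1), (4,2,1); hand-derived distances:
  # d(A,B) = d(C,D) = 1 - 4.5/sqrt(21); d(A,C) = 2;
  # d(A,D) = d(B,C) = 1 + 4.5/sqrt(21); d(B,D) = 27/14
  w <- cbind(A = c(1, 2, 3), B = c(1, 2, 4), C = c(3, 2, 1), D = c(4, 2, 1))
  sc <- cluster_samples(w, metric = "correlation", linkage = "average")
  d_near <- 1 - 4.5 / sqrt(21)
  final <- (2 + 2 * (1 + 4.5 / sqrt(21)) + 27 / 14) / 4
  expect_equal(sc$tree$height, c(d_near, d_near, final), tolerance = 1e-12)
  # the two merges at d_near are the pairs {A,B} and {C,D}
  lab <- cut_clusters(sc, 2)
  expect_equal(unname(lab["A"]), unname(lab["B"]))
  expect_equal(unname(lab["C"]), unname(lab["D"]))
  expect_true(lab["A"] != lab["C"])
})

test_that("too-few samples and degenerate profiles are rejected", {
  expect_error(cluster_samples(cbind(a = c(1, 2), b = c(2, 1))), "at least 3")
  w <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1), d = c(2, 1, 3))
  expect_error(cluster_samples(w, metric = "correlation"), "constant weight.*a")
  w0 <- cbind(a = c(0, 0, 0), b = c(1, 2, 3), c = c(3, 2, 1), d = c(2, 1, 3))
  expect_error(cluster_samples(w0, metric = "correlation"), "all-zero")
})

test_that("cophenetic correlation is exactly 1 on ultrametric distances", {
  m <- matrix(10, 6, 6)
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 2
  diag(m) <- 0
  d <- as_labeled_dist(m, paste0("s", 1:6))
  tree <- stats::hclust(d, method = "average")
  expect_equal(cophenetic_correlation(tree, d), 1.0, tolerance = 1e-9)
})

test_that("cophenetic correlation matches a by-hand computation on 4 points", {
  # merges: {1,2} at 1, {3,4} at 2, all at mean(9,10,10,11) = 10
  m <- matrix(0, 4, 4)
  m[1, 2] <- 1; m[3, 4] <- 2
  m[1, 3] <- 9; m[1, 4] <- 10; m[2, 3] <- 10; m[2, 4] <- 11
  m <- m + t(m)
  d <- as_labeled_dist(m, paste0("s", 1:4))
  tree <- stats::hclust(d, method = "average")
  orig <- c(1, 9, 10, 10, 11, 2)   # pairs (12,13,14,23,24,34)
  coph <- c(1, 10, 10, 10, 10, 2)  # lowest-common-merge heights, by hand
  # Pearson correlation by its definition
  ox <- orig - mean(orig); oy <- coph - mean(coph)
  r_hand <- sum(ox * oy) / sqrt(sum(ox^2) * sum(oy^2))
  expect_equal(cophenetic_correlation(tree, d), r_hand, tolerance = 1e-12)
})

test_that("degenerate distance configurations raise the documented errors", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  d <- as_labeled_dist(m, paste0("s", 1:4))
  tree <- stats::hclust(d, method = "average")
  expect_error(cophenetic_correlation(tree, d), "zero variance")
  expect_error(cophenetic_correlation(tree, stats::dist(matrix(1:3))), "4 samples")
})

test_that("cophenetic correlation is invariant under sample relabeling", {
  gt <- generate_ground_truth(n_metabolites = 50, n_group_a = 5, n_group_b = 5,
                              n_signatures = 3, seed = 8)
  ss <- extract_signatures(render_matrix(gt), 3, seed = 8, n_restarts = 4)
  cc1 <- cluster_samples(ss)$cophenetic_coefficient
  perm <- metabosig:::with_seed(42, sample(ncol(ss$weights)))
  cc2 <- cluster_samples(ss$weights[, perm])$cophenetic_coefficient
  expect_equal(cc1, cc2, tolerance = 1e-12)
})

test_that("cluster cuts recover block structure and saturate correctly", {
  # two duplicated blocks of samples
  w <- cbind(a1 = c(5, 1, 1), a2 = c(5, 1, 1), a3 = c(5.1, 1, 1),
             b1 = c(1, 1, 6), b2 = c(1, 1, 6), b3 = c(1, 1, 6.2))
  sc <- cluster_samples(w, metric = "euclidean")
  lab <- cut_clusters(sc, 2)
  expect_length(unique(lab[1:3]), 1)
  expect_length(unique(lab[4:6]), 1)
  expect_true(lab[1] != lab[4])

  # saturation: every sample its own cluster
  w5 <- cbind(a = c(1, 9, 1), b = c(9, 1, 1), c = c(1, 1, 9),
              d = c(5, 5, 1), e = c(1, 5, 5))
  sc5 <- cluster_samples(w5, metric = "euclidean")
  lab5 <- cut_clusters(sc5, 5)
  expect_length(unique(lab5), 5)
  expect_error(cut_clusters(sc5, 1), "n_clusters")
  expect_error(cut_clusters(sc5, 7), "n_clusters")
})

test_that("the automatic cut recovers the planted two-group split", {
  gt <- generate_ground_truth(seed = 31)
  ss <- extract_signatures(render_matrix(gt), 5, seed = 31)
  lab <- cut_clusters(cluster_samples(ss))
  expect_identical(attr(lab, "k"), 2L)
  a <- gt$group_labels == "A"
  expect_length(unique(lab[a]), 1)
  expect_length(unique(lab[!a]), 1)
  expect_true(lab[a][1] != lab[!a][1])
})

test_that("centroids are percent compositions with exact arithmetic", {
  w <- cbind(s1 = c(1, 1), s2 = c(3, 1))
  cent <- cluster_centroids(w, c(1, 1))
  expect_equal(unname(cent[1, ]), c(62.5, 37.5))

  # singleton cluster: centroid equals the normalized sample
  cent2 <- cluster_centroids(w, c(1, 2))
  expect_equal(unname(cent2[2, ]), c(75, 25))

  gt <- generate_ground_truth(seed = 3)
  cent3 <- cluster_centroids(gt$true_weights,
                             ifelse(gt$group_labels == "A", 1, 2))
  expect_true(all(abs(rowSums(cent3) - 100) < 1e-9))

  w0 <- cbind(s1 = c(0, 0), s2 = c(1, 1))
  expect_error(cluster_centroids(w0, c(1, 1)), "s1")
})

test_that("dendrograms export to Newick with sample ids as tips", {
  w <- cbind(a = c(1, 5, 1), b = c(1, 5, 2), c = c(6, 1, 1), d = c(6, 1, 2))
  sc <- cluster_samples(w, metric = "euclidean")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(sc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
})
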