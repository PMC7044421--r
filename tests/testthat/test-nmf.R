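test_that("an exact rank-1 matrix is fit to numerical precision", {
  x <- outer(c(1, 2), c(3, 1, 2))
  fit <- nmf_once(x, 1, seed = 1)
  expect_lt(fit$relative_error, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("a planted positive 4x4 rank-2 product is recovered to low error", {
  set.seed(42)
  w0 <- matrix(runif(8, 0.5, 2), 4, 2)
  h0 <- matrix(runif(8, 0.5, 2), 2, 4)
  x <- w0 %*% h0
  ss <- extract_signatures(x, 2, seed = 1, n_restarts = 10,
                           max_iter = 5000, tol = 1e-9)
  expect_lt(ss$reconstruction_error, 1e-4)
})

test_that("degenerate inputs and invalid ranks are rejected", {
  x <- matrix(c(1, 2, 0, 3, 1, 0), 2, 3, byrow = TRUE) # zero column 3
  expect_error(nmf_once(x, 1), "all-zero column")
  x2 <- rbind(c(1, 2), c(0, 0))
  expect_error(nmf_once(x2, 1), "all-zero row")
  x3 <- matrix(runif(12), 3, 4)
  expect_error(nmf_once(x3, 5), "rank k")
  expect_error(nmf_once(x3, 0), "k")
  x3[1, 1] <- NA
  expect_error(nmf_once(x3, 2), "missing")
})

test_that("the multiplicative-update loss is non-increasing on every run", {
  for (seed in 1:5) {
    x <- metabosig:::with_seed(seed, matrix(stats::rexp(30 * 8), 30, 8))
    fit <- nmf_once(x, 3, seed = seed)
    expect_true(all(diff(fit$loss_trace) <= 1e-10),
                label = sprintf("monotone trace (seed %d)", seed))
  }
  gt <- generate_ground_truth(n_metabolites = 60, n_group_a = 5, n_group_b = 5,
                              n_signatures = 4, seed = 6)
  fit <- nmf_once(render_matrix(gt), 4, seed = 6)
  expect_true(all(diff(fit$loss_trace) <= 1e-10))
})

test_that("normalization yields probability columns and preserves the product", {
  w <- cbind(c(2, 2, 4), c(1, 1, 2))
  h <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  ss <- normalize_factorization(w, h)
  expect_equal(unname(ss$signatures[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(unname(ss$weights[1, ]), h[1, ] * 8)
  expect_equal(ss$signatures %*% ss$weights, w %*% h, tolerance = 1e-10,
               ignore_attr = TRUE)

  fit <- nmf_once(matrix(runif(24) + 0.1, 6, 4), 2, seed = 2)
  ss2 <- normalize_factorization(fit$W, fit$H)
  expect_true(all(abs(colSums(ss2$signatures) - 1) < 1e-9))
  expect_equal(ss2$signatures %*% ss2$weights, fit$W %*% fit$H, tolerance = 1e-10)

  w0 <- cbind(c(1, 1), c(0, 0))
  expect_error(normalize_factorization(w0, matrix(1, 2, 2)), "degenerate signature")
})

test_that("signature matching recovers permutations and matches brute force", {
  a <- metabosig:::with_seed(5, matrix(runif(18), 6, 3))
  expect_identical(match_signatures(a, a)$permutation, 1:3)
  expect_equal(match_signatures(a, a)$total_similarity, 3, tolerance = 1e-12)

  shifted <- a[, c(2, 3, 1)]
  expect_identical(match_signatures(a, shifted)$permutation, c(3L, 1L, 2L))

  b <- metabosig:::with_seed(6, matrix(runif(18), 6, 3))
  got <- match_signatures(a, b)
  # independent brute force over all 6 permutations
  cs <- crossprod(sweep(a, 2, sqrt(colSums(a^2)), "/"),
                  sweep(b, 2, sqrt(colSums(b^2)), "/"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p) sum(cs[cbind(1:3, p)]), numeric(1))
  expect_identical(got$permutation, as.integer(perms[[which.max(scores)]]))
  expect_equal(got$total_similarity, max(scores), tolerance = 1e-12)

  expect_error(match_signatures(a, a[, 1:2]), "identical dimensions")
})

test_that("recovered signatures track planted rows under row permutation", {
  gt <- generate_ground_truth(n_metabolites = 40, n_group_a = 5, n_group_b = 5,
                              n_signatures = 3, seed = 14)
  x <- render_matrix(gt)$values
  perm <- metabosig:::with_seed(14, sample(nrow(x)))
  s1 <- extract_signatures(x, 3, seed = 14, n_restarts = 6, tol = 1e-8)$signatures
  s2 <- extract_signatures(x[perm, ], 3, seed = 14, n_restarts = 6, tol = 1e-8)$signatures
  # the initialization is not row-permuted with X, so the two runs follow
  # different trajectories to the same optimum: compare matched columns
  mt <- match_signatures(s1[perm, ], s2)
  cs <- metabosig:::cosine_similarity_matrix(s1[perm, ], s2)
  expect_true(all(cs[cbind(1:3, mt$permutation)] > 0.999))
})

test_that("bootstrap stability separates planted structure from noise", {
  gt <- generate_ground_truth(n_metabolites = 80, n_group_a = 8, n_group_b = 8,
                              n_signatures = 3, noise_sigma = 0, seed = 17)
  x <- render_matrix(gt)
  bs <- bootstrap_stability(x, 3, n_boot = 10, seed = 17, n_restarts = 5)
  expect_true(all(bs$per_signature_silhouette > 0.9))

  noise <- metabosig:::with_seed(18, matrix(stats::rexp(80 * 16), 80, 16))
  bs_noise <- bootstrap_stability(noise, 3, n_boot = 10, seed = 17, n_restarts = 5)
  expect_lt(mean(bs_noise$per_signature_silhouette),
            mean(bs$per_signature_silhouette))

  expect_error(bootstrap_stability(x, 3, n_boot = 1, seed = 1), "n_boot")
})

test_that("rank selection recovers trivial and planted ranks", {
  gt1 <- generate_ground_truth(n_metabolites = 30, n_group_a = 4, n_group_b = 4,
                               n_signatures = 1, noise_sigma = 0, seed = 2)
  x1 <- render_matrix(gt1)
  rr1 <- suppressWarnings(select_rank(x1, ranks = 1:3, n_boot = 8, seed = 2,
                                      n_restarts = 4))
  expect_identical(rr1$selected_rank, 1L)

  gt3 <- generate_ground_truth(n_metabolites = 100, n_group_a = 6, n_group_b = 6,
                               n_signatures = 3, noise_sigma = 0.1, seed = 3)
  rr3 <- suppressWarnings(select_rank(render_matrix(gt3), ranks = 2:6,
                                      n_boot = 10, seed = 3, n_restarts = 5))
  expect_identical(rr3$selected_rank, 3L)

  expect_error(select_rank(render_matrix(gt3), ranks = integer(0)), "empty rank")
})
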