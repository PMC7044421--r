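test_that("Student t matches the closed-form pooled-variance computation", {
  m <- tiny_matrix()
  res <- differential_abundance(m, "A", "B")
  r1 <- res[res$metabolite == "m1", ]
  # A = (1,2,3), B = (2,3,4): mean diff -1, pooled SD 1, t = -1.2247, df 4
  expect_equal(r1$t, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(r1$df, 4)
  expect_equal(r1$p, 0.2879, tolerance = 1e-3)
  oracle <- student_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$t, oracle$t, tolerance = 1e-12)
  expect_equal(r1$p, oracle$p, tolerance = 1e-12)
  # fold change: A mean 5 vs B mean 10 on m2
  expect_equal(res[res$metabolite == "m2", "fold_change"], 0.5)
})

test_that("identical groups fall back to the zero-variance convention", {
  m <- tiny_matrix() # m3 is constant 2 in both groups
  res <- differential_abundance(m, "A", "B")
  r3 <- res[res$metabolite == "m3", ]
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_identical(r3$stars, "")
})

test_that("star codes follow the p-value thresholds", {
  expect_identical(metabosig:::star_code(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
                   c("", "*", "**", "***", "****"))
})

test_that("student and welch agree at equal variances and sizes", {
  v <- matrix(c(1, 2, 3, 4, 3, 4, 5, 6), 1, 8,
              dimnames = list("m1", paste0("s", 1:8)))
  g <- stats::setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  m <- metabolite_matrix(v, groups = g)
  rs <- differential_abundance(m, "A", "B", test = "student")
  rw <- differential_abundance(m, "A", "B", test = "welch")
  expect_equal(rs$t, rw$t, tolerance = 1e-12)
  expect_equal(rs$p, rw$p, tolerance = 1e-12)
})

test_that("per-sample common scaling leaves ratios and their tests invariant", {
  m <- tiny_matrix()
  r1 <- metabolite_ratio(m, "m1", "m2")
  scl <- c(2, 5, 0.5, 1.2, 3, 10)
  m2 <- metabolite_matrix(sweep(m$values, 2, scl, "*"), m$metabolite_ids,
                          m$sample_ids, groups = m$groups)
  r2 <- metabolite_ratio(m2, "m1", "m2")
  expect_equal(r1$per_sample, r2$per_sample, tolerance = 1e-12)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("precursor-product percentages and SEM follow their definitions", {
  m <- tiny_matrix()
  # product = precursor in every sample -> 100% everywhere, SEM 0
  r <- precursor_product_ratio(m, "m1", "m1")
  expect_true(all(r$per_sample == 100))
  expect_true(all(r$summary$sem == 0))
  expect_identical(r$dispersion, "sem")

  # precursor (2,4), product (6,12): 300% each, SEM 0
  v <- matrix(c(2, 4, 6, 12), 2, 2, byrow = TRUE,
              dimnames = list(c("pre", "prod"), c("s1", "s2")))
  g <- stats::setNames(c("A", "A"), c("s1", "s2"))
  m2 <- metabolite_matrix(v, groups = g)
  r2 <- precursor_product_ratio(m2, "pre", "prod", groups = "A")
  expect_equal(unname(r2$per_sample), c(300, 300))
  expect_equal(r2$summary$mean, 300)
  expect_equal(r2$summary$sem, 0)

  expect_error(precursor_product_ratio(m, "nope", "m1"), "not found")
  v0 <- v; v0["pre", 1] <- 0
  m0 <- metabolite_matrix(v0, groups = g)
  expect_error(precursor_product_ratio(m0, "pre", "prod", groups = "A"), "s1")
})

test_that("metabolite ratios behave on identities and planted differences", {
  m <- tiny_matrix()
  r <- metabolite_ratio(m, "m1", "m1")
  expect_true(all(r$per_sample == 1))
  expect_equal(r$p, 1) # identical ratios -> zero-variance convention
  expect_identical(r$dispersion, "sd")

  # ratios (1,1,1) vs (2,2,2.0001): p matches the closed-form oracle
  v <- matrix(c(1, 1, 1, 2, 2, 2.0001, rep(1, 6)), 2, 6, byrow = TRUE,
              dimnames = list(c("num", "den"), paste0("s", 1:6)))
  g <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  m2 <- metabolite_matrix(v, groups = g)
  r2 <- metabolite_ratio(m2, "num", "den")
  oracle <- student_oracle(c(1, 1, 1), c(2, 2, 2.0001))
  expect_equal(r2$t, oracle$t, tolerance = 1e-9)
  expect_equal(r2$p, oracle$p, tolerance = 1e-9)
})

test_that("a planted threefold group effect attains the smallest p", {
  # structureless baseline: per-metabolite constant level with 10%
  # multiplicative noise, then a 3x shift planted in group A for met0007
  v <- metabosig:::with_seed(13, {
    base <- stats::runif(60, 0.5, 5)
    base * exp(matrix(stats::rnorm(60 * 15, 0, 0.1), 60, 15))
  })
  ids <- sprintf("met%04d", 1:60)
  samples <- sprintf("s%02d", 1:15)
  groups <- stats::setNames(rep(c("A", "B"), c(8, 7)), samples)
  v[7, groups == "A"] <- v[7, groups == "A"] * 3
  m <- metabolite_matrix(v, ids, samples, groups = groups)
  res <- differential_abundance(m, "A", "B")
  expect_identical(res$metabolite[which.min(res$p)], "met0007")
  expect_identical(res$stars[res$metabolite == "met0007"], "****")
})
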