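test_that("pearson_correlation matches the textbook formula", {
  x <- 1:10
  expect_equal(pearson_correlation(x, x * 2 + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  # frozen from direct evaluation of the product-moment and t formulas
  x <- c(1.371, -0.565, 0.363, 0.633, 0.404, -0.106, 1.512, -0.095,
         2.018, -0.063)
  y <- c(2.676, 1.722, -1.026, 0.354, 0.271, 0.53, 1.228, -2.751,
         -0.422, 1.257)
  res <- pearson_correlation(x, y)
  expect_equal(res$r, 0.146836010743, tolerance = 1e-10)
  expect_equal(res$p, 0.685632510699, tolerance = 1e-9)
  expect_equal(res$n, 10)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("Mantel exact p equals full 4!-enumeration oracle", {
  set.seed(71)
  for (k in 1:5) {
    pts_a <- matrix(rnorm(8), 4, 2)
    pts_b <- pts_a + matrix(rnorm(8, sd = 0.8), 4, 2)
    a <- as.matrix(dist(pts_a))
    b <- as.matrix(dist(pts_b))
    res <- mantel_test(a, b, exact = TRUE)
    expect_equal(res$p, mantel_exact_oracle(a, b), tolerance = 1e-12)
    expect_equal(res$n_perm, 24)
  }
})

test_that("Mantel r and conventions", {
  set.seed(72)
  a <- as.matrix(dist(rnorm(8)))
  res <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)                     # minimal attainable p
  # r equals the plain Pearson correlation of the upper triangles
  b <- as.matrix(dist(rnorm(8)))
  expect_equal(mantel_test(a, b, n_perm = 9, seed = 1)$r,
               cor(a[upper.tri(a)], b[upper.tri(b)]))
  # simultaneous relabeling of both matrices leaves r unchanged
  idx <- sample(8)
  expect_equal(mantel_test(a[idx, idx], b[idx, idx], n_perm = 9, seed = 1)$r,
               mantel_test(a, b, n_perm = 9, seed = 1)$r)
  expect_error(mantel_test(a, matrix(0, 8, 8), n_perm = 9), "constant")
  expect_error(mantel_test(a[1:3, 1:3], b[1:3, 1:3]), "at least 4")
})

test_that("Mantel agrees with vegan on a fixture", {
  skip_if_not_installed("vegan")
  set.seed(73)
  x <- matrix(rpois(60, 5), 10, 6)
  a <- as.matrix(vegan::vegdist(x, "bray"))
  b <- as.matrix(dist(rnorm(10)))
  ours <- mantel_test(a, b, n_perm = 999, seed = 4)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  # p-values are independent permutation estimates of the same quantity
  expect_lt(abs(ours$p - ref$signif), 0.1)
})

test_that("PERMANOVA on Euclidean distances reproduces classical ANOVA F", {
  set.seed(81)
  for (k in 1:10) {
    groups <- rep(c("a", "b", "c"), times = sample(3:6, 3, replace = TRUE))
    values <- rnorm(length(groups), mean = as.integer(factor(groups)))
    d <- as.matrix(dist(values))
    res <- permanova_oneway(d, groups, n_perm = 19, seed = k)
    expect_equal(res$pseudo_f, anova_f_oracle(values, groups),
                 tolerance = 1e-10)
    expect_equal(res$df_between, 2)
    expect_equal(res$df_within, length(groups) - 3)
  }
})

test_that("PERMANOVA separates duplicated-column groups and validates", {
  # two groups of 8 duplicated columns: within-group distances all zero,
  # so pseudo-F is maximal and only the 2/choose(16,8) label permutations
  # reproducing the partition can match it
  m <- cbind(matrix(rep(c(5, 0, 2), 8), 3), matrix(rep(c(0, 4, 1), 8), 3))
  ct <- count_table(m)
  d <- dissimilarity_matrix(ct)
  groups <- rep(c("g1", "g2"), each = 8)
  res <- permanova_oneway(d, groups, n_perm = 999, seed = 1)
  expect_gt(res$pseudo_f, 100)
  expect_lt(res$p, 0.01)
  expect_error(permanova_oneway(d, c("a", rep("b", 15)), n_perm = 9),
               "singleton")
  expect_error(permanova_oneway(d, rep("a", 16), n_perm = 9), "2 groups")
})

test_that("PERMANOVA matches vegan::adonis2 pseudo-F", {
  skip_if_not_installed("vegan")
  set.seed(82)
  x <- matrix(rpois(15 * 8, 6), 15, 8)
  groups <- rep(c("a", "b", "c"), each = 5)
  d <- as.matrix(vegan::vegdist(x, "bray"))
  ours <- permanova_oneway(d, groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ groups, permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("Tukey HSD letters match pairwise significance", {
  set.seed(91)
  # identical means: one shared letter
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  res <- anova_tukey(v, g)
  expect_true(all(res$summary$letters == res$summary$letters[1]))

  # far-separated groups: all letters distinct
  v <- c(rnorm(10), rnorm(10, 50), rnorm(10, 100))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- anova_tukey(v, g)
  expect_equal(length(unique(res$summary$letters)), 3)

  # letters consistent with the pairwise HSD p-values: two groups share a
  # letter exactly when their comparison is not significant
  for (k in 1:10) {
    v <- rnorm(36, mean = rep(sample(0:3, 3, replace = TRUE), each = 12))
    g <- rep(c("a", "b", "c"), each = 12)
    res <- anova_tukey(v, g)
    lt <- setNames(strsplit(res$summary$letters, ""), res$summary$group)
    for (r in seq_len(nrow(res$pairwise))) {
      share <- length(intersect(lt[[res$pairwise$group1[r]]],
                                lt[[res$pairwise$group2[r]]])) > 0
      expect_equal(share, res$pairwise$p_adj[r] >= res$alpha)
    }
  }
  expect_error(anova_tukey(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5)),
               "zero within-group variance")
})

test_that("Tukey group means/SE match direct computation", {
  set.seed(92)
  v <- rnorm(24, rep(c(0, 2), each = 12))
  g <- rep(c("lo", "hi"), each = 12)
  res <- anova_tukey(v, g)
  expect_equal(res$summary$mean[res$summary$group == "lo"],
               mean(v[g == "lo"]))
  expect_equal(res$summary$se[res$summary$group == "hi"],
               sd(v[g == "hi"]) / sqrt(12))
})

test_that("fit_log_model recovers noiseless and noisy coefficients", {
  x <- c(1, 2, 4, 8, 16, 32)
  res <- suppressWarnings(fit_log_model(x, 2 + 3 * log(x)))  # noiseless: perfect-fit warning expected
  expect_equal(res$slope, 3, tolerance = 1e-10)
  expect_equal(res$intercept, 2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)

  res0 <- suppressWarnings(fit_log_model(x, rep(5, 6)))
  expect_equal(res0$r_squared, 0)

  # normal-equations oracle on a noisy fixture
  set.seed(93)
  x <- runif(40, 1, 30)
  y <- 1.5 - 0.4 * log(x) + rnorm(40, sd = 0.3)
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- fit_log_model(x, y)
  expect_equal(res$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$slope, beta[2], tolerance = 1e-10)
  expect_error(fit_log_model(c(-1, 2, 3), 1:3), "positive")
  expect_error(fit_log_model(rep(2, 5), rnorm(5)), "constant x")
})
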