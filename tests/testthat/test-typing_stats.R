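# K-means typing and the statistical tests, cross-checked against base-R
# implementations as independent oracles.

test_that("kmeans_two_types separates obvious clusters and handles edge cases", {
  X <- data.frame(total_length = c(0, 0, 10, 10), branch_count = c(0, 1, 10, 11))
  ta <- kmeans_two_types(X, seed = 1)
  expect_equal(unname(ta$type[1]), unname(ta$type[2]))
  expect_equal(unname(ta$type[3]), unname(ta$type[4]))
  expect_false(ta$type[1] == ta$type[3])
  ## tie in sizes: type 1 is the smaller-mean-length cluster
  expect_equal(unname(ta$type[1]), 1L)
  ## exactly two distinct points -> singleton clusters
  ta2 <- kmeans_two_types(data.frame(total_length = c(1, 100),
                                     branch_count = c(1, 50)), seed = 1)
  expect_equal(sort(ta2$cluster_means$size), c(1L, 1L))
  ## duplicated dataset preserves the partition structure
  ta3 <- kmeans_two_types(X[rep(1:4, 2), ], seed = 1)
  expect_equal(unname(ta3$type[1:4]), unname(ta3$type[5:8]))
  expect_error(kmeans_two_types(X[c(1, 1), ], seed = 1), "distinct")
})

test_that("kmeans typing matches the exhaustive two-partition optimum on 4 points", {
  X <- data.frame(total_length = c(0, 0, 10, 10), branch_count = c(0, 1, 10, 11))
  Z <- scale(as.matrix(X))
  ## enumerate all 2-cluster assignments, minimizing within-cluster SS
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^4 - 2)) {
    a <- as.integer(intToBits(code)[1:4]) + 1L
    if (length(unique(a)) < 2) next
    ss <- sum(sapply(split(seq_len(4), a), function(ix) {
      if (length(ix) == 1) return(0)
      sum(scale(Z[ix, , drop = FALSE], scale = FALSE)^2)
    }))
    if (ss < best_ss) { best_ss <- ss; best <- a }
  }
  ta <- kmeans_two_types(X, seed = 1)
  expect_equal(ari(ta$type, best), 1)
})

test_that("kmeans typing recovers the planted mixture across 10 seeds", {
  for (s in 1:10) {
    mix <- generate_type_mixture(seed = 40 + s)
    ta <- kmeans_two_types(mix, seed = 40 + s)
    expect_lte(sum(ta$type != mix$component), 3)
  }
})

test_that("rank_sum_test: exact enumeration and approximation", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")
  ## a sample versus itself (ties -> approximate path) gives p = 1
  same <- c(1, 2, 3, 4, 5, 6, 7)
  expect_equal(rank_sum_test(same, same)$p_value, 1, tolerance = 1e-9)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
  ## exact p equals wilcox.test's exact p on untied small samples
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(rank_sum_test(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  ## exact and normal-approximation p agree within 0.02 at n = 6 vs 6
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    exact_p <- rank_sum_test(a, b)$p_value
    approx_p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
  ## large samples use the tie-corrected approximation; oracle: wilcox.test
  set.seed(4)
  a <- round(rnorm(15), 1); b <- round(rnorm(20), 1)
  expect_equal(rank_sum_test(a, b)$p_value,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("rank-sum null rejection rate is nominal", {
  set.seed(7)
  rej <- mean(replicate(2000, {
    rank_sum_test(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("pooled_t_test matches hand computation and t.test oracle", {
  r <- pooled_t_test(rnorm(27), rnorm(45))
  expect_equal(r$df, 70)
  r2 <- pooled_t_test(c(1, 2), c(3, 4))
  expect_equal(r2$statistic, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(r2$df, 2)
  set.seed(5)
  a <- rnorm(10, 1); b <- rnorm(12)
  o <- stats::t.test(a, b, var.equal = TRUE)
  r3 <- pooled_t_test(a, b)
  expect_equal(r3$statistic, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r3$p_value, o$p.value, tolerance = 1e-12)
  expect_error(pooled_t_test(c(1, 1), c(1, 1)), "variance")
  expect_error(pooled_t_test(1, c(1, 2)), "n >= 2")
})

test_that("pooled t type-I error at the study sample sizes is nominal", {
  set.seed(8)
  rej <- mean(replicate(2000, {
    pooled_t_test(rnorm(27), rnorm(45))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("bh_fdr matches the step-up hand computation and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    ## order invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pearson_correlation matches cor.test and handles extremes", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_correlation(x, -x)$estimate, -1)
  expect_equal(pearson_correlation(x, -x)$p_value, 0)
  x2 <- c(1, 2, 3, 4); y2 <- c(1, 3, 2, 5)
  r <- pearson_correlation(x2, y2)
  o <- stats::cor.test(x2, y2)
  expect_equal(r$estimate, unname(o$estimate), tolerance = 1e-12)
  expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
  ## direct covariance-formula oracle
  r_direct <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  expect_equal(r$estimate, r_direct, tolerance = 1e-12)
  expect_error(pearson_correlation(1:5, rep(1, 5)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "length >= 3")
})
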