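test_that("pairwise correlations match hand computations", {
  m <- cbind(a = 1:5, b = c(2, 4, 6, 8, 10), c = 5:1, flat = rep(2, 5))
  rownames(m) <- paste0("W", 1:5)
  r <- pairwise_corr(m)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_true(is.na(r["a", "flat"]))
  expect_error(pairwise_corr(m[1:2, ]), "3 wells")
  expect_error(pairwise_corr(m, genes = "zz"), "zz")
})

test_that("exhaustive permutation p matches brute-force enumeration", {
  m <- cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  rownames(m) <- paste0("W", 1:4)
  res <- perm_corr_test(m, cbind("x", "y"), exhaustive = TRUE)
  # 24 permutations; only identity and a compensating one reach |r| = 1
  expect_equal(res$p_emp, 2 / 24)
  expect_equal(res$r_obs, 1)
  expect_equal(res$n_perm, 24)
})

test_that("sampled permutation p approaches the exhaustive value", {
  set.seed(7)
  for (n in 4:6) {
    x <- stats::rnorm(n)
    y <- x + stats::rnorm(n, 0, 0.8)
    m <- cbind(x = x, y = y)
    rownames(m) <- paste0("W", seq_len(n))
    exact <- perm_corr_test(m, cbind("x", "y"), exhaustive = TRUE)$p_emp
    sampled <- perm_corr_test(m, cbind("x", "y"), n_perm = 50000,
                              seed = n)$p_emp
    expect_lt(abs(sampled - exact), 0.01)
  }
})

test_that("permutation test is seed-deterministic and floors p", {
  sim <- simulate_qpcr(qpcr_sim_config(n_wells = 80, p_detect = 0.9,
                                       seed = 15))
  expr <- to_expression(sim$ct)
  pairs <- rbind(c("BCL11B", "TBR1"), c("CUX1", "SATB2"),
                 c("MAP2", "NCAM1"))
  r1 <- perm_corr_test(expr, pairs, n_perm = 500, seed = 77)
  r2 <- perm_corr_test(expr, pairs, n_perm = 500, seed = 77)
  expect_identical(r1, r2)
  expect_true(all(r1$p_emp[r1$evaluable] >= 1 / 501))

  # a zero-variance gene is excluded from the family, not the output
  pairs2 <- rbind(c("MAP2", "ALB"), c("MAP2", "NCAM1"))
  r3 <- perm_corr_test(expr, pairs2, n_perm = 100, seed = 1)
  expect_false(r3$evaluable[1])
  expect_true(is.na(r3$q[1]))
  expect_equal(r3$q[2], r3$p_emp[2])  # BH over a family of one
})

test_that("empirical p decreases as the observed correlation grows", {
  set.seed(5)
  n <- 40
  x <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  lam <- c(0, 0.3, 0.6, 1, 2)
  ps <- vapply(lam, function(l) {
    m <- cbind(x = x, y = l * x + noise)
    rownames(m) <- paste0("W", seq_len(n))
    perm_corr_test(m, cbind("x", "y"), n_perm = 2000, seed = 9)$p_emp
  }, numeric(1))
  rs <- vapply(lam, function(l) abs(stats::cor(x, l * x + noise)),
               numeric(1))
  expect_true(all(diff(ps[order(rs)]) <= 0))
})

test_that("detection-mode correlation equals phi on the binary calls", {
  sim <- simulate_qpcr(qpcr_sim_config(n_wells = 120, p_detect = 0.7,
                                       seed = 19))
  expr <- to_expression(sim$ct)
  res <- perm_corr_test(expr, cbind("GAD1", "SLC17A7"), n_perm = 50,
                        seed = 2, mode = "detection")
  expect_equal(res$r_obs,
               stats::cor((expr[, "GAD1"] > 0) + 0,
                          (expr[, "SLC17A7"] > 0) + 0))
  expect_equal(attr(res, "mode"), "detection")
})

test_that("BH adjustment agrees with a brute-force step-up", {
  set.seed(11)
  for (i in 1:50) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_step_up(p))
  }
})

test_that("PCA matches an eigendecomposition oracle and fixes signs", {
  set.seed(3)
  m <- matrix(stats::rnorm(60), 10, 6,
              dimnames = list(paste0("W", 1:10), paste0("g", 1:6)))
  pc <- pca_expr(m, n_components = 3)
  ev <- eigen(stats::cov(m))
  expect_equal(pc$var_explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  for (j in 1:3) {
    expect_equal(abs(pc$loadings[, j]), abs(ev$vectors[, j]),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  # scores reproduce the centred projection
  centred <- scale(m, scale = FALSE)
  expect_equal(pc$scores, centred %*% pc$loadings, ignore_attr = TRUE)
})

test_that("PCA variance spectrum is rotation invariant; degenerate errors", {
  set.seed(4)
  m <- matrix(stats::rnorm(80), 20, 4,
              dimnames = list(paste0("W", 1:20), paste0("g", 1:4)))
  q <- qr.Q(qr(matrix(stats::rnorm(16), 4, 4)))
  rot <- m %*% q
  dimnames(rot) <- dimnames(m)
  expect_equal(pca_expr(m, 4)$var_explained,
               pca_expr(rot, 4)$var_explained, tolerance = 1e-10)

  line <- cbind(g1 = 1:10, g2 = 2 * (1:10))
  rownames(line) <- paste0("W", 1:10)
  expect_equal(pca_expr(line, 2)$var_explained[1], 1)
  const <- matrix(5, 4, 3, dimnames = list(paste0("W", 1:4),
                                           paste0("g", 1:3)))
  expect_error(pca_expr(const), "no variance")
})

test_that("cluster separation test distinguishes separated groups", {
  set.seed(21)
  a <- matrix(stats::rnorm(200), 100, 2)
  b <- matrix(stats::rnorm(200, mean = 10), 100, 2)
  res <- cluster_separation_test(rbind(a, b),
                                 rep(c("a", "b"), each = 100))
  expect_lt(res$p.value, 1e-6)
  expect_true(all(res$d_own >= 0))

  # shuffled labels on the same data lose the separation signal
  set.seed(22)
  ps <- replicate(100, {
    lab <- sample(rep(c("a", "b"), each = 100))
    cluster_separation_test(rbind(a, b), lab)$p.value
  })
  expect_gt(stats::median(ps), 0.1)

  expect_error(cluster_separation_test(rbind(a, b),
                                       rep(c("a", "b"), c(198, 2))),
               "at least 3")
  expect_error(cluster_separation_test(a, rep("a", 100)), "two groups")
  res2 <- cluster_separation_test(rbind(a, b),
                                  rep(c("a", "b"), each = 100),
                                  paired = FALSE)
  expect_equal(res2$test, "wilcoxon-rank-sum")
})
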