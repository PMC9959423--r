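test_that("compute_beta matches the two-pass variance oracle", {
  expect_equal(compute_beta(matrix(c(0, 2), 2, 1)), 1)
  expect_warning(b0 <- compute_beta(matrix(1, 3, 4)), "degenerate")
  expect_equal(b0, 0)
  set.seed(11)
  X <- matrix(rnorm(500 * 6), 500, 6)
  xbar <- colMeans(X)
  oracle <- sum(apply(X, 1, function(r) sum((r - xbar)^2))) / nrow(X)
  expect_equal(compute_beta(X), oracle, tolerance = 1e-12)
})

test_that("membership update obeys symmetry, singularity, and hand values", {
  # equidistant from two centroids
  u <- update_fcm_memberships(matrix(0, 1, 1), matrix(c(-1, 1), 2, 1), m = 1.5)
  expect_equal(unname(u[1, ]), c(0.5, 0.5))
  # sample at a centroid
  u <- update_fcm_memberships(matrix(1, 1, 1), matrix(c(1, 4, 9), 3, 1), m = 2)
  expect_equal(unname(u[1, ]), c(1, 0, 0))
  # 1-D hand evaluation: x = 0, centroids -1 and 3, m = 2 -> (9/10, 1/10)
  u <- update_fcm_memberships(matrix(0, 1, 1), matrix(c(-1, 3), 2, 1), m = 2)
  expect_equal(unname(u[1, ]), c(0.9, 0.1))
})

test_that("membership update reduces to textbook FCM at m = 2", {
  set.seed(5)
  X <- matrix(runif(40 * 3), 40, 3)
  C <- matrix(runif(4 * 3), 4, 3)   # off-sample: no zero distances
  u <- update_fcm_memberships(X, C, m = 2)
  # direct textbook evaluation
  d2 <- as.matrix(fluoroseg:::pairwise_sq_dists(X, C))
  ref <- t(apply(d2, 1, function(row) {
    (1 / row) / sum(1 / row)
  }))
  expect_equal(unname(u), unname(ref), tolerance = 1e-9)
})

test_that("typicality update follows the possibilistic exponential", {
  p <- upfc_params()  # b = 0.5, n = 1.5
  C4 <- matrix(c(1, 10, 20, 30), 4, 1)
  t_ <- update_pca_typicalities(matrix(0, 1, 1), C4, beta = 2, p)
  # d2 = 1, N_C = 4 -> exponent -(0.5*1.5*2/2) = -0.75
  expect_equal(t_[1, 1], exp(-0.75), tolerance = 1e-12)
  # typicality 1 at the centroid, strictly decreasing with distance
  t2 <- update_pca_typicalities(matrix(c(1, 2, 5), 3, 1),
                                matrix(1, 1, 1), beta = 2, p)
  expect_equal(t2[1, 1], 1)
  expect_true(all(diff(t2[, 1]) < 0))
  expect_error(update_pca_typicalities(matrix(0), matrix(1), 0, p), "beta")
})

test_that("centroid update is a weighted mean with sensible degenerate cases", {
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  u <- matrix(0.5, 4, 2)
  t_ <- matrix(0.5, 4, 2)
  cn <- update_centroids(X, u, t_, upfc_params())
  expect_equal(unname(cn[, 1]), c(1.5, 1.5))  # equal weights -> mean
  cn1 <- update_centroids(matrix(5, 1, 1), matrix(1, 1, 1),
                          matrix(1, 1, 1), upfc_params())
  expect_equal(cn1[1, 1], 5)
  # all-zero weight column keeps the previous centroid
  expect_warning(
    cnz <- update_centroids(X, matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2),
                            matrix(0, 4, 2), upfc_params(a = 1, b = 0 + 1e-12),
                            centroids = matrix(c(0, 9), 2, 1)),
    "all-zero")
  expect_equal(cnz[2, 1], 9)
})

test_that("full UPFC recovers separated blobs and keeps invariants", {
  set.seed(21)
  n <- 120
  mu1 <- c(0.2, 0.2, 0.2, 0.1, 0.1, 0.2)
  mu2 <- c(0.8, 0.8, 0.8, 0.9, 0.7, 0.8)
  X <- rbind(sweep(matrix(rnorm(n * 6, 0, 0.02), n, 6), 2, mu1, "+"),
             sweep(matrix(rnorm(n * 6, 0, 0.02), n, 6), 2, mu2, "+"))
  fit <- run_upfc(X, 2, seed = 3)
  # each centroid within 3 standard errors of a blob mean
  se <- 0.02 / sqrt(n) * 3
  m1 <- colMeans(X[1:n, ]); m2 <- colMeans(X[(n + 1):(2 * n), ])
  d <- fluoroseg:::pairwise_sq_dists(fit$centroids, rbind(m1, m2))
  expect_true(all(apply(sqrt(d), 1, min) < 3 * sqrt(6) * 0.02 / sqrt(n) * 3 + se))
  # row-stochastic memberships
  expect_true(all(abs(rowSums(fit$u_fcm) - 1) < 1e-9))
  expect_true(all(fit$u_fcm >= 0 & fit$u_fcm <= 1))
  expect_true(all(fit$u_pca > 0 & fit$u_pca <= 1))
  # full objective non-increasing along the iteration trace
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # centroids inside the data bounding box
  expect_true(all(fit$centroids >= matrix(apply(X, 2, min),
                                          nrow(fit$centroids), 6, TRUE) - 1e-12))
  expect_true(all(fit$centroids <= matrix(apply(X, 2, max),
                                          nrow(fit$centroids), 6, TRUE) + 1e-12))
  expect_error(run_upfc(X, 1), "n_clusters")
  expect_error(run_upfc(X, nrow(X)), "n_clusters")
})

test_that("row-stochasticity and objective monotonicity hold on pixel data", {
  pix <- small_pixels(n = c(80, 80, 40, 30, 40))
  for (k in c(3, 8)) {
    fit <- run_upfc(pix$x, k, seed = k)
    expect_true(all(abs(rowSums(fit$u_fcm) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})
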