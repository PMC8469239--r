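test_that("squared pairwise distances match hand values and brute force", {
  d <- pairwise_sq_euclidean(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 25)
  expect_equal(d[2, 1], 25)
  expect_identical(diag(d), c(0, 0))

  same <- pairwise_sq_euclidean(rbind(c(1, 2), c(1, 2)))
  expect_equal(same[1, 2], 0)

  set.seed(11)
  X <- matrix(stats::rnorm(15), 5, 3)
  expect_lt(max(abs(pairwise_sq_euclidean(X) - brute_sq_dist(X))), 1e-10)

  expect_error(pairwise_sq_euclidean(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(pairwise_sq_euclidean(matrix(1, 1, 3)), ">= 2 samples")
})

test_that("local connectivity is the off-diagonal row minimum", {
  d <- matrix(c(0, 4, 1, 9,
                4, 0, 2, 2,
                1, 2, 0, 5,
                9, 2, 5, 0), 4, byrow = TRUE)
  expect_equal(local_connectivity(d), c(1, 2, 1, 2))

  d2 <- matrix(2, 4, 4); diag(d2) <- 0
  expect_equal(local_connectivity(d2), rep(2, 4))

  set.seed(2)
  X <- matrix(stats::rnorm(40), 8)
  dr <- pairwise_sq_euclidean(X)
  brute <- sapply(1:8, function(i) min(dr[i, -i]))
  expect_equal(local_connectivity(dr), brute)
})

test_that("smooth neighbor count behaves at its fixed points and is monotone in sigma", {
  # single other sample at exactly rho: p = 1, k = 2
  nc <- neighbor_count(d_row = 3, rho = 3, sigma = 0.5)
  expect_equal(nc$p, 1)
  expect_equal(nc$k, 2)
  # all others at rho: k = 2^(n-1) regardless of sigma
  for (s in c(0.1, 1, 10)) {
    expect_equal(neighbor_count(rep(5, 7), 5, s)$k, 2^7)
  }
  # doubling sigma never decreases k
  set.seed(4)
  d_row <- sort(stats::runif(20, 0.5, 8))
  k1 <- neighbor_count(d_row, min(d_row), 0.7)$k
  k2 <- neighbor_count(d_row, min(d_row), 1.4)$k
  expect_gte(k2, k1)
  expect_error(neighbor_count(d_row, min(d_row), 0), "sigma")
})

test_that("bandwidth binary search hits the neighbor-count target", {
  set.seed(8)
  X <- matrix(stats::rnorm(150), 30, 5)
  d <- pairwise_sq_euclidean(X)
  rho <- local_connectivity(d)
  for (i in 1:30) {
    cal <- calibrate_sigma(d[i, -i], rho[i], k_target = 15, tol = 1e-4)
    expect_true(cal$converged)
    expect_lte(abs(neighbor_count(d[i, -i], rho[i], cal$sigma)$k - 15), 1e-3)
    # oracle: re-run at 10x iterations reaches the same count
    cal10 <- calibrate_sigma(d[i, -i], rho[i], 15, tol = 1e-6, max_iter = 2000)
    expect_lt(abs(cal10$k - cal$k), 1e-3)
  }
})

test_that("degenerate and limit cases of the calibration are handled", {
  # all distances at rho: every conditional probability is exp(0) = 1, so
  # the count is pinned at 2^(n-1) whatever sigma does -> non-converged flag
  cal <- calibrate_sigma(rep(2, 16), 2, k_target = 15)
  expect_false(cal$converged)
  expect_equal(cal$k, 2^16)
  # k_target = n - 1 with distinct distances converges via the large-sigma limit
  d_row <- c(1, 2, 3, 5, 8)
  cal2 <- calibrate_sigma(d_row, 1, k_target = 5, tol = 1e-4)
  expect_true(cal2$converged)
  expect_lte(abs(cal2$k - 5), 1e-3)
  expect_error(calibrate_sigma(c(1, 2), 1, k_target = 10), "unreachable")
})

test_that("fuzzy graph uses mean symmetrization and keeps its contract", {
  # n = 2: each sample's only neighbor sits exactly at its rho, so the
  # conditional probabilities are 1 whatever the bandwidth does
  d <- matrix(c(0, 4, 4, 0), 2)
  fg2 <- suppressWarnings(fuzzy_graph(d, k_target = 1))
  expect_equal(fg2$P[1, 2], 1)
  expect_equal(fg2$P[2, 1], 1)

  # mean symmetrization: conditional 1.0 and 0.5 -> 0.75, not fuzzy union 1.0
  p12 <- 1.0; p21 <- 0.5
  expect_equal((p12 + p21) / 2, 0.75)
  expect_false(isTRUE(all.equal((p12 + p21) / 2, p12 + p21 - p12 * p21)))

  set.seed(6)
  X <- matrix(stats::rnorm(120), 24, 5)
  fg <- fuzzy_graph(pairwise_sq_euclidean(X), k_target = 10)
  expect_equal(max(abs(fg$P - t(fg$P))), 0)
  expect_identical(unname(diag(fg$P)), rep(0, 24))
  expect_true(all(fg$P >= 0 & fg$P <= 1))
  expect_true(all(fg$sigma > 0))
  expect_equal(fg$rho, local_connectivity(pairwise_sq_euclidean(X)))
})

test_that("low-dimensional kernel fit reproduces the min_dist target curve", {
  k <- fit_low_dim_kernel(0.25)
  expect_gt(k$a, 0)
  expect_gt(k$b, 0)
  # functional form forces g(0) = 1
  expect_equal(1 / (1 + k$a * 0^(2 * k$b)), 1)
  # fit quality against the piecewise target over the fitting grid
  d <- seq(0, 3, by = 0.01)
  h <- ifelse(d <= 0.25, 1, exp(-(d - 0.25)))
  g <- 1 / (1 + k$a * d^(2 * k$b))
  expect_lte(sqrt(mean((g - h)^2)), 0.02)
  # oracle: independent nls fit on a finer grid agrees on the curve shape
  dd <- seq(0, 3, by = 0.002)
  hh <- ifelse(dd <= 0.25, 1, exp(-(dd - 0.25)))
  fit <- stats::nls(hh ~ 1 / (1 + a * dd^(2 * b)), start = list(a = 1, b = 1))
  co <- stats::coef(fit)
  g2 <- 1 / (1 + co["a"] * d^(2 * co["b"]))
  expect_lt(max(abs(g - g2)), 0.05)
  expect_error(fit_low_dim_kernel(-1), "min_dist")
})

test_that("normalized Q has unit off-diagonal mass and hand-checkable raw values", {
  k1 <- structure(list(a = 1, b = 1, min_dist = NA), class = "LowDimKernel")
  Y <- rbind(c(0, 0), c(1, 0), c(0, 0))
  lq <- low_dim_probabilities(Y, k1)
  expect_equal(lq$w[1, 2], 1 / 2)   # distance 1, a = b = 1
  expect_equal(lq$w[1, 3], 1)       # coincident points
  expect_equal(sum(lq$Q), 1, tolerance = 1e-12)

  set.seed(10)
  Y2 <- matrix(stats::rnorm(30), 15, 2)
  lq2 <- low_dim_probabilities(Y2, fit_low_dim_kernel(0.25))
  expect_lt(abs(sum(lq2$Q) - 1), 1e-12)
  expect_identical(unname(diag(lq2$Q)), rep(0, 15))
})

test_that("cross-entropy matches the scalar double-loop oracle and Gibbs bounds", {
  set.seed(12)
  P <- matrix(stats::runif(36), 6); P <- (P + t(P)) / 2; diag(P) <- 0
  Q <- matrix(stats::runif(36), 6); Q <- (Q + t(Q)) / 2; diag(Q) <- 0
  expect_lt(abs(cross_entropy(P, Q) - brute_cross_entropy(P, Q)), 1e-10)
  expect_lt(abs(cross_entropy(P, P)), 1e-6)
  expect_gt(cross_entropy(P, Q), 0)
})

test_that("analytic gradient equals central finite differences", {
  kernel <- fit_low_dim_kernel(0.25)
  set.seed(21)
  for (rep in 1:3) {
    n <- 10
    P <- matrix(stats::runif(n * n), n); P <- (P + t(P)) / 2; diag(P) <- 0
    Y <- matrix(stats::rnorm(n * 2), n)
    g <- ce_gradient(P, Y, kernel)
    fd <- fd_gradient(P, Y, kernel)
    expect_lte(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
  # symmetric two-point configuration: equal and opposite forces
  P2 <- matrix(c(0, 0.6, 0.6, 0), 2)
  Y2 <- rbind(c(-1, 0), c(1, 0))
  g2 <- ce_gradient(P2, Y2, kernel)
  expect_equal(g2[1, ], -g2[2, ], tolerance = 1e-12)
  # concentrated P: gradient still matches finite differences
  P3 <- matrix(0, 5, 5); P3[1, 2] <- P3[2, 1] <- 0.9
  set.seed(22)
  Y3 <- matrix(stats::rnorm(10), 5)
  expect_lte(max(abs(ce_gradient(P3, Y3, kernel) - fd_gradient(P3, Y3, kernel))) /
               max(abs(fd_gradient(P3, Y3, kernel))), 1e-4)
})

test_that("gradient descent reduces the cross-entropy and is seed-deterministic", {
  co <- simulate_cohort(small_spec(seed = 14))
  X <- t(log2(co$expression$values + 1))
  emb <- umap_embed(X, n_neighbors = 10, n_epochs = 50, seed = 3)
  expect_length(emb$ce_trace, 51)
  expect_lt(emb$ce_trace[51], emb$ce_trace[1])
  expect_true(all(is.finite(emb$Y)))
  emb2 <- umap_embed(X, n_neighbors = 10, n_epochs = 50, seed = 3)
  expect_identical(emb$Y, emb2$Y)
  emb3 <- umap_embed(X, n_neighbors = 10, n_epochs = 50, seed = 4)
  expect_false(identical(emb$Y, emb3$Y))
})

test_that("embedding is equivariant under feature-order permutation", {
  co <- simulate_cohort(small_spec(seed = 15))
  X <- t(log2(co$expression$values + 1))
  set.seed(1)
  Xp <- X[, sample(ncol(X))]
  e1 <- umap_embed(X, n_neighbors = 8, n_epochs = 30, seed = 5)
  e2 <- umap_embed(Xp, n_neighbors = 8, n_epochs = 30, seed = 5)
  # summation order changes distances at machine precision and the descent
  # amplifies it slightly; agreement to 1e-4 relative is equivariance here
  expect_equal(e1$Y, e2$Y, tolerance = 1e-4)
})

test_that("well-separated planted clusters separate in the embedding", {
  co <- simulate_cohort(small_spec(seed = 16, fc = 4))
  lab <- co$truth$cluster_label
  emb <- embed_expression(co$expression, seed = 16, n_epochs = 200)
  Y <- emb$Y
  c1 <- colMeans(Y[lab == "1", ]); c2 <- colMeans(Y[lab == "2", ])
  within <- mean(c(sqrt(rowSums(sweep(Y[lab == "1", ], 2, c1)^2)),
                   sqrt(rowSums(sweep(Y[lab == "2", ], 2, c2)^2))))
  expect_gte(sqrt(sum((c1 - c2)^2)) / within, 2)
})
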