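test_that("objective matches closed forms and the brute-force oracle", {
  # two points on the line, one center at the midpoint
  X <- matrix(c(0, 1), ncol = 1)
  expect_equal(kmor_objective(X, c(1L, 1L), matrix(0.5), gamma = 2.5), 0.5)
  # second point an outlier, center at 0: S = 0 so D = 0 and P = 0
  expect_equal(kmor_objective(X, c(1L, 2L), matrix(0), gamma = 2.5), 0)
  expect_error(kmor_objective(X, c(2L, 2L), matrix(0), gamma = 2.5),
               "outlier cluster")

  for (seed in 1:5) {
    X <- random_matrix(seed, 20, 2)
    fit <- kmor_fit(X, kmor_config(k = 2, n0_fraction = 0.1, seed = seed))
    expect_equal(
      kmor_objective(X, fit$assignments, fit$centers, 2.5),
      brute_kmor_objective(X, fit$assignments, fit$centers, 2.5),
      tolerance = 1e-12)
    # the recomputed objective reproduces the trace's last entry
    expect_equal(
      kmor_objective(X, fit$assignments, fit$centers, 2.5),
      fit$objective_trace[fit$n_iterations],
      tolerance = 1e-9)
  }
})

test_that("5-point instance: best-of-restarts recovers the enumerated optimum", {
  x <- c(0, 1, 10, 11, 100)
  opt <- enumerate_kmor_optimum(x, k = 2, gamma = 2.5, n0 = 1)
  expect_identical(opt$outliers, 5L)
  expect_equal(opt$centers, c(0.5, 10.5))

  sel <- kmor_select_k(matrix(x), 2,
                       kmor_config(gamma = 2.5, n0_fraction = 0.2, seed = 1))
  fit <- sel$results[["2"]]
  expect_identical(fit$outlier_indices, 5L)
  expect_equal(sort(as.numeric(fit$centers)), c(0.5, 10.5))
  expect_equal(fit$objective_trace[fit$n_iterations], opt$P, tolerance = 1e-9)
})

test_that("objective trace is non-increasing and the outlier cap holds", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(20:60, 1); d <- sample(1:3, 1); k <- sample(1:3, 1)
    X <- random_matrix(seed, n, d)
    fit <- kmor_fit(X, kmor_config(k = k, n0_fraction = 0.1, seed = seed))
    tr <- fit$objective_trace
    if (length(tr) > 1) {
      expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
    }
    expect_lte(length(fit$outlier_indices), floor(0.1 * n))
  }
})

test_that("with n0 = 0 and shared init, KMOR reproduces Lloyd's K-means", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(15:40, 1); d <- sample(1:2, 1); k <- sample(2:3, 1)
    X <- random_matrix(seed, n, d)
    init <- X[sample(n, k), , drop = FALSE]
    fit <- kmor_fit(X, kmor_config(k = k, n0_fraction = 0, seed = seed),
                    init_centers = init)
    ref <- lloyd_kmeans(X, init)
    expect_identical(fit$assignments, ref$assignments)
    expect_equal(fit$centers, ref$centers, tolerance = 1e-12)
    expect_length(fit$outlier_indices, 0)
  }
})

test_that("Rule-1 consistency holds at convergence", {
  for (seed in 1:10) {
    X <- random_matrix(seed, 50, 2)
    fit <- kmor_fit(X, kmor_config(k = 2, n0_fraction = 0.1, seed = seed))
    D2 <- matrix(NA_real_, 50, 2)
    for (j in 1:2) D2[, j] <- rowSums(sweep(X, 2, fit$centers[j, ])^2)
    dmin <- apply(D2, 1, min)
    inl <- setdiff(seq_len(50), fit$outlier_indices)
    # every non-outlier sits at its nearest center
    expect_true(all(abs(D2[cbind(inl, fit$assignments[inl])] - dmin[inl]) < 1e-12))
    # outliers are exactly the farthest points: rank separation
    if (length(fit$outlier_indices)) {
      expect_gt(min(dmin[fit$outlier_indices]), max(dmin[inl]))
    }
    # and, unless the n0 cap forced far points to stay (flagged on the
    # result), no retained point lies beyond the reported threshold
    if (!fit$cap_applied) {
      expect_true(all(dmin[inl] <= fit$d_threshold_final + 1e-9))
    }
  }
})

test_that("degenerate and boundary configurations behave", {
  X <- random_matrix(1, 5, 2)
  # n = k: perfect fit, zero objective, no outliers
  fit <- kmor_fit(X, kmor_config(k = 5, seed = 1))
  expect_equal(fit$objective_trace[fit$n_iterations], 0)
  expect_length(fit$outlier_indices, 0)
  expect_error(kmor_fit(X, kmor_config(k = 6)), "exceed")
  expect_error(kmor_config(n0_fraction = 1), "n0_fraction")
  expect_error(kmor_config(gamma = 0), "gamma")

  # n0_fraction = 0 -> never any outliers
  expect_length(kmor_outliers(X, kmor_config(k = 2, n0_fraction = 0)), 0)
})

test_that("KMOR flags a planted far outlier and respects determinism", {
  g <- generate_synthetic(synthetic_spec(n_target = 200, n_features = 2,
                                         outlier_fraction = 0.005,
                                         outlier_distance = 10, seed = 9))
  planted <- which(g$truth$outlier)
  out <- kmor_outliers(g$dataset$features, kmor_config(k = 1, seed = 4))
  expect_true(all(planted %in% out))
  expect_lte(length(out), floor(0.05 * 200))

  f1 <- kmor_fit(g$dataset$features, kmor_config(k = 2, seed = 11))
  f2 <- kmor_fit(g$dataset$features, kmor_config(k = 2, seed = 11))
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("k selection returns the argmin of its own objective curve", {
  g <- generate_synthetic(synthetic_preset("two_blobs", seed = 3))
  sel <- kmor_select_k(g$dataset$features, 1:3, kmor_config(seed = 7))
  expect_identical(sel$k_best,
                   as.integer(names(which.min(sel$objectives))))
  # the separated-blob structure makes k = 1 catastrophically worse
  expect_gt(sel$objectives[["1"]], 100 * sel$objectives[["2"]])
  expect_gte(sel$k_best, 2L)

  expect_identical(kmor_select_k(g$dataset$features, 1,
                                 kmor_config(seed = 7))$k_best, 1L)

  # duplicating the dataset leaves the argmin unchanged
  X2 <- rbind(g$dataset$features, g$dataset$features)
  sel2 <- kmor_select_k(X2, 1:3, kmor_config(seed = 7))
  expect_identical(sel2$k_best, sel$k_best)
})
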