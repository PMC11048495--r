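test_that("IQR fences on 1-NN distances flag the hand example", {
  # distances {1,1,1,1,97}: Q3 = 1, IQR = 0, fence = 1 -> only 97 exceeds
  X <- matrix(c(0, 1, 2, 3, 100), ncol = 1)
  expect_identical(iqr_outliers(X), 5L)

  # equally spaced grid: all 1-NN distances equal, fence not exceeded
  expect_length(iqr_outliers(matrix(seq(0, 9), ncol = 1)), 0)
  expect_error(iqr_outliers(matrix(1:3, ncol = 1)), "at least 4")

  # documented blindness: a tight pair of far outliers shields itself
  # (each is the other's nearest neighbor at distance 0)
  Xp <- matrix(c(0, 1, 2, 3, 100, 100), ncol = 1)
  expect_length(iqr_outliers(Xp), 0)
})

test_that("proxy datasets recover planted outliers", {
  g <- generate_synthetic(synthetic_preset("blob_with_outliers", seed = 1))
  planted <- which(g$truth$outlier)
  expect_length(planted, 5)

  pk <- build_proxy_dataset(g$dataset$features, "kmor",
                            kmor_config(k = 1, seed = 1), k_candidates = 1)
  expect_identical(which(pk$proxy_labels == "proxy-outlier"), planted)
  expect_identical(pk$source, "kmor")

  # the IQR detector flags at least the planted points (plus possibly a
  # few genuine distance-tail points of the clean blob)
  pi <- build_proxy_dataset(g$dataset$features, "iqr")
  expect_true(all(planted %in% which(pi$proxy_labels == "proxy-outlier")))

  # zero detected outliers -> all-target with a warning
  tight <- matrix(seq(0, 1, length.out = 20), ncol = 1)
  expect_warning(p0 <- build_proxy_dataset(tight, "iqr"), "no outliers")
  expect_true(all(p0$proxy_labels == "target"))
})

separable_proxy <- function(seed = 1) {
  g <- generate_synthetic(synthetic_preset("blob_with_outliers", seed = seed))
  build_proxy_dataset(g$dataset$features, "kmor",
                      kmor_config(k = 1, seed = seed), k_candidates = 1)
}

test_that("optimize_jk cells agree with an independent fold-by-fold rescore", {
  px <- separable_proxy(1)
  jk <- optimize_jk(px, J_values = 1:3, K_values = 1:3, inner_folds = 2,
                    seed = 1)

  # the returned pair is the argmax of the score matrix it reports
  sm <- jk$grid$score_matrix
  expect_equal(sm[as.character(jk$J_best), as.character(jk$K_best)],
               max(sm, na.rm = TRUE))

  # independent recomputation of the (1,1) cell: same folds, explicit loop
  folds_id <- oclab:::stratified_folds(px$proxy_labels, 2, 1)
  g <- vapply(1:2, function(f) {
    tr <- which(folds_id != f & px$proxy_labels == "target")
    va <- which(folds_id == f)
    m <- ocnn_fit(px$features[tr, , drop = FALSE], 1, 1, theta = 1)
    pred <- ifelse(ocnn_classify(m, px$features[va, , drop = FALSE]) == "target",
                   "target", "proxy-outlier")
    cts <- confusion(px$proxy_labels[va], pred, positive = "proxy-outlier")
    gmeans(cts$TP / (cts$TP + cts$FN), cts$TN / (cts$TN + cts$FP))
  }, numeric(1))
  expect_equal(sm[1, 1], mean(g), tolerance = 1e-12)

  # proxies 10 sigma out are always rejected in every grid cell's CV, so
  # every defined cell score is bounded below by sqrt(0) yet the top cells
  # track specificity; the best cell dominates (1,1)
  expect_gte(max(sm, na.rm = TRUE), sm[1, 1])

  # single-cell grid
  one <- optimize_jk(px, 1, 1, inner_folds = 2, seed = 1)
  expect_identical(c(one$J_best, one$K_best), c(1L, 1L))
})

test_that("optimize_jk breaks score ties toward the smallest J then K", {
  px <- separable_proxy(1)
  jk <- optimize_jk(px, 1:4, 1:4, inner_folds = 2, seed = 1)
  sm <- jk$grid$score_matrix
  best <- max(sm, na.rm = TRUE)
  hits <- which(sm == best, arr.ind = TRUE)
  expect_identical(jk$J_best, as.integer(min(hits[, "row"])))
  expect_identical(jk$K_best,
                   as.integer(min(hits[hits[, "row"] == min(hits[, "row"]),
                                       "col"])))
})

test_that("unfittable (J, K) cells are excluded, not scored", {
  px <- separable_proxy(1)
  # inner 2-fold training folds hold ~47 target rows: J+K = 60 unfittable
  jk <- optimize_jk(px, J_values = c(1, 30), K_values = c(1, 30),
                    inner_folds = 2, seed = 1)
  expect_true(is.na(jk$grid$score_matrix["30", "30"]))
  expect_false(is.na(jk$grid$score_matrix["1", "1"]))
})

test_that("optimize_theta separates the construction and achieves G-means 1", {
  px <- separable_proxy(1)
  sc <- optimize_theta(px, inner_folds = 2, seed = 1)
  t_scores <- sc$point_scores[sc$point_labels == "target"]
  p_scores <- sc$point_scores[sc$point_labels == "proxy-outlier"]
  # chosen threshold sits above every target ratio and is attained by the
  # smallest proxy ratio (candidates are the ratios themselves)
  expect_gt(sc$theta_best, max(t_scores))
  expect_lte(sc$theta_best, min(p_scores))
  expect_equal(max(sc$gmeans_by_candidate, na.rm = TRUE), 1)
  expect_true(sc$theta_best %in% sc$candidates)
  # applying the threshold to the pooled CV decisions is perfect
  expect_equal(oclab:::proxy_gmeans(sc$point_labels,
                                    sc$point_scores < sc$theta_best), 1)
})

test_that("theta scan candidate bookkeeping and degenerate fallbacks", {
  px <- separable_proxy(2)
  sc <- optimize_theta(px, inner_folds = 2, seed = 2)
  expect_length(sc$gmeans_by_candidate, length(sc$candidates))
  expect_lte(length(sc$candidates), length(px$proxy_labels))

  # no proxy-outliers at all -> fallback theta with warning
  allt <- structure(list(features = matrix(rnorm(40), 20),
                         proxy_labels = rep("target", 20), source = "iqr"),
                    class = "proxy_dataset")
  expect_warning(sc0 <- optimize_theta(allt, 2, 1), "fallback|no proxy")
  expect_equal(sc0$theta_best, 1.5)
  expect_warning(jk0 <- optimize_jk(allt, 1:2, 1:2, 2, 1), "no proxy")
  expect_identical(c(jk0$J_best, jk0$K_best), c(1L, 1L))
})

test_that("tuning is deterministic given proxy and seed", {
  px <- separable_proxy(3)
  a <- optimize_jk(px, 1:3, 1:3, 2, seed = 5)
  b <- optimize_jk(px, 1:3, 1:3, 2, seed = 5)
  expect_identical(a$grid$score_matrix, b$grid$score_matrix)
  sa <- optimize_theta(px, 2, seed = 5)
  sb <- optimize_theta(px, 2, seed = 5)
  expect_identical(sa$theta_best, sb$theta_best)
  expect_identical(sa$candidates, sb$candidates)
})
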