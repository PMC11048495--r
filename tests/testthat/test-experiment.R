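# A small separable dataset keeps the harness tests fast.
small_separable <- function(seed = 1) {
  generate_synthetic(synthetic_preset("separable", seed = seed,
                                      n_target = 80, n_minority = 20))$dataset
}

test_that("stratified outer folds partition each round exactly", {
  ds <- small_separable()
  for (r in 1:3) {
    folds <- oclab:::stratified_folds(ds$labels, 5, r)
    expect_identical(sort(unlist(lapply(1:5, function(f) which(folds == f)))),
                     seq_along(ds$labels))
    # stratification keeps positives in every fold (20 positives, 5 folds)
    expect_true(all(vapply(1:5, function(f) {
      any(ds$labels[folds == f] == "positive")
    }, TRUE)))
  }
})

test_that("one-class training never sees a positive row", {
  ds <- small_separable()
  # poison every positive row with a sentinel coordinate; if any entered a
  # one-class fit, the fitted scaler/thresholds would shift detectably.
  p <- oclab:::fold_pieces(ds, seq_along(ds$labels), 1:10, scale = FALSE)
  expect_identical(nrow(p$train), sum(ds$labels == "negative"))
  poisoned <- ds
  poisoned$features[poisoned$labels == "positive", ] <- 1e6
  pp <- oclab:::fold_pieces(poisoned, seq_along(ds$labels), 1:10, scale = FALSE)
  expect_identical(p$train, pp$train)
})

test_that("11NN experiment runs, aggregates, and is seed-deterministic", {
  ds <- small_separable()
  cfg <- experiment_config("11NN", outer_folds = 5, rounds = 2, seed = 7)
  a <- run_ocnn_experiment(ds, cfg)
  expect_s3_class(a, "run_record")
  expect_identical(nrow(a$per_fold), 10L)
  # minority offset 10 sd: recall is perfect even for plain 11NN
  expect_equal(a$aggregate$recall$mean, 1)
  expect_gte(a$aggregate$auc$mean, 0.95)

  b <- run_ocnn_experiment(ds, cfg)
  expect_identical(a$per_fold, b$per_fold)

  # aggregate mean/sd match the per-fold pool
  g <- a$per_fold[, "gmeans"]
  expect_equal(a$aggregate$gmeans$mean, mean(g))
  expect_equal(a$aggregate$gmeans$sd, sd(g))
})

test_that("tuned variants and leave-one-out boundary run to completion", {
  ds <- small_separable()
  rec <- run_ocnn_experiment(ds, experiment_config("JKNN", outer_folds = 2,
                                                   rounds = 1, seed = 3,
                                                   J_values = 1:2,
                                                   K_values = 1:2))
  expect_identical(nrow(rec$per_fold), 2L)
  expect_gte(rec$aggregate$gmeans$mean, 0.8)

  # leave-one-out on a 10-row toy: folds without positives are skipped
  toy <- generate_synthetic(synthetic_preset("separable", seed = 2,
                                             n_target = 8, n_minority = 2))$dataset
  w <- testthat::capture_warnings(
    loo <- run_ocnn_experiment(toy, experiment_config("11NN", outer_folds = 10,
                                                      rounds = 1, seed = 1,
                                                      scale = FALSE)))
  expect_true(all(grepl("no positives: skipped", w)))
  expect_gt(length(w), 0)
  expect_identical(nrow(loo$per_fold) + loo$n_skipped_folds, 10L)
})

test_that("LBNN harness: Q = 0 accepted sets nest inside Q = 1", {
  ds <- small_separable()
  fid <- oclab:::stratified_folds(ds$labels, 5, 1)
  tr <- which(fid != 1); te <- which(fid == 1)
  p <- oclab:::fold_pieces(ds, tr, te, scale = FALSE)
  m0 <- lbnn_fit(p$train, Q = 0, k = 2, kmor_config = kmor_config(seed = 1),
                 scale = FALSE)
  m1 <- lbnn_fit(p$train, Q = 1, k = 2, kmor_config = kmor_config(seed = 1),
                 scale = FALSE)
  a0 <- lbnn_classify(m0, p$test)
  a1 <- lbnn_classify(m1, p$test)
  expect_true(all(a1 >= a0))
})

test_that("run records convert to writable report records", {
  ds <- small_separable()
  rec <- run_lbnn_experiment(ds, experiment_config("LBNN", rounds = 1, seed = 5))
  r <- as_report_record(rec)
  expect_identical(r$method, "LBNN")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(r), path)
  back <- read_report(path)
  expect_equal(back[[1]]$metrics$gmeans$mean, rec$aggregate$gmeans$mean)
  expect_identical(back[[1]]$config$seed, 5L)
})

test_that("wrapped baselines follow the protocol when available", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  ds <- small_separable()
  for (method in c("OCSVM", "LR", "SVM", "RF")) {
    rec <- run_baselines(ds, experiment_config(method, outer_folds = 3,
                                               rounds = 1, seed = 11))
    expect_s3_class(rec, "run_record")
    # the construction is separable: every baseline ranks it perfectly
    expect_gte(rec$aggregate$auc$mean, 0.95)
    if (method != "OCSVM") {
      # binary baselines also classify near-perfectly; OC-SVM at nu = 0.5
      # deliberately rejects ~half the target region, depressing G-means
      expect_gte(rec$aggregate$gmeans$mean, 0.9)
    } else {
      expect_gte(rec$aggregate$recall$mean, 0.95)
    }
  }
  # seeded determinism for the stochastic baseline
  cfg <- experiment_config("RF", outer_folds = 3, rounds = 1, seed = 11)
  expect_identical(run_baselines(ds, cfg)$per_fold,
                   run_baselines(ds, cfg)$per_fold)
})
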