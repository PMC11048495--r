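# Repeated stratified cross-validation harness.
#
# Outer protocol (shared by every method): per round, a seeded stratified
# split into `outer_folds` folds; per fold, one-class methods are fitted on
# the negative (target) training rows only, tuned on proxy outliers where
# the variant calls for it, and evaluated on the held-out mixed fold.
# Metrics are pooled over rounds x folds and reported as mean and sample
# standard deviation.

#' Experiment configuration
#'
#' Defaults reproduce the package's reference protocol: 5 outer folds,
#' 2 inner folds, 10 rounds, KMOR with `n0 = 0.05 * n`, `gamma = 2.5`,
#' at most 100 iterations, `theta = 1` for the JKNN variants, and an
#' OC-SVM baseline with `nu = 0.5` and kernel coefficient `1/d`.
#'
#' @param method One of `"11NN"`, `"11NN_theta"`, `"JKNN"`,
#'   `"11NN_theta_kmor"`, `"JKNN_kmor"`, `"LBNN"`, `"OCSVM"`, `"LR"`,
#'   `"SVM"`, `"RF"`.
#' @param outer_folds Outer CV folds (default 5).
#' @param inner_folds Inner CV folds used by proxy tuning (default 2).
#' @param rounds Number of CV repetitions (default 10).
#' @param seed Integer master seed.
#' @param J_values,K_values Grids searched by [optimize_jk()] for the JKNN
#'   variants.
#' @param theta_fallback Fallback threshold when the theta scan is
#'   degenerate (default 1.5).
#' @param Q LBNN percentile rank (default 0.9).
#' @param k_candidates KMOR cluster-count candidates (default `1:3`).
#' @param kmor KMOR settings, a [kmor_config()].
#' @param scale Standardize features per fold using target-class training
#'   statistics (default `TRUE`).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(method = "LBNN", outer_folds = 5L,
                              inner_folds = 2L, rounds = 10L, seed = 42L,
                              J_values = 1:10, K_values = 1:10,
                              theta_fallback = 1.5, Q = 0.9,
                              k_candidates = 1:3,
                              kmor = kmor_config(), scale = TRUE) {
  methods <- c("11NN", "11NN_theta", "JKNN", "11NN_theta_kmor", "JKNN_kmor",
               "LBNN", "OCSVM", "LR", "SVM", "RF")
  if (!method %in% methods) {
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  }
  structure(list(method = method, outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 rounds = as.integer(rounds), seed = as.integer(seed),
                 J_values = J_values, K_values = K_values,
                 theta_fallback = theta_fallback, Q = Q,
                 k_candidates = k_candidates, kmor = kmor, scale = scale),
            class = "experiment_config")
}

# Iterate rounds x folds, calling `fit_eval(train_idx, test_idx, seed)` which
# must return an `evaluation_report` or NULL (fold skipped).
run_protocol <- function(dataset, config, fit_eval) {
  labels <- dataset$labels
  fold_reports <- list()
  provenance <- list()
  skipped <- 0L
  for (r in seq_len(config$rounds)) {
    round_seed <- derive_seed(config$seed, r)
    folds_id <- stratified_folds(labels, config$outer_folds, round_seed)
    for (f in seq_len(config$outer_folds)) {
      test_idx <- which(folds_id == f)
      train_idx <- which(folds_id != f)
      if (!any(labels[test_idx] == "positive")) {
        warning(sprintf("round %d fold %d has no positives: skipped", r, f))
        skipped <- skipped + 1L
        next
      }
      fold_rep <- fit_eval(train_idx, test_idx, derive_seed(round_seed, f))
      if (is.null(fold_rep)) { skipped <- skipped + 1L; next }
      fold_reports[[length(fold_reports) + 1L]] <- fold_rep
      provenance[[length(provenance) + 1L]] <- list(round = r, fold = f)
    }
  }
  aggregate_run(dataset$name, config, fold_reports, provenance, skipped)
}

aggregate_run <- function(dataset_name, config, fold_reports, provenance,
                          skipped) {
  metrics <- c("accuracy", "precision", "recall", "specificity", "gmeans", "auc")
  per_fold <- matrix(NA_real_, nrow = length(fold_reports),
                     ncol = length(metrics), dimnames = list(NULL, metrics))
  for (m in metrics) {
    per_fold[, m] <- vapply(fold_reports, function(fr) fr[[m]] %||% NA_real_,
                            numeric(1))
  }
  agg <- lapply(metrics, function(m) {
    v <- per_fold[, m]
    v <- v[!is.na(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) stats::sd(v) else NA_real_,
         n_defined = length(v),
         n_excluded = nrow(per_fold) - length(v))
  })
  names(agg) <- metrics
  structure(
    list(dataset = dataset_name, method = config$method,
         aggregate = agg, per_fold = per_fold,
         fold_reports = fold_reports, provenance = provenance,
         n_skipped_folds = skipped,
         config = list(method = config$method, outer_folds = config$outer_folds,
                       inner_folds = config$inner_folds, rounds = config$rounds,
                       seed = config$seed)),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s on %s (%d folds evaluated, %d skipped)\n",
              x$method, x$dataset, nrow(x$per_fold), x$n_skipped_folds))
  for (m in names(x$aggregate)) {
    a <- x$aggregate[[m]]
    cat(sprintf("  %-11s %.3f (%.3f)\n", m, a$mean, a$sd %||% NA))
  }
  invisible(x)
}

#' Convert a run record to a report record
#'
#' Flattens the aggregate of a [run_ocnn_experiment()] /
#' [run_lbnn_experiment()] result into the record structure consumed by
#' [write_report()].
#'
#' @param record A `run_record`.
#' @return A named list (one report record).
#' @export
as_report_record <- function(record) {
  stopifnot(inherits(record, "run_record"))
  list(dataset = record$dataset, method = record$method,
       metrics = record$aggregate, config = record$config,
       n_folds_evaluated = nrow(record$per_fold),
       n_folds_skipped = record$n_skipped_folds)
}

# Shared per-fold preparation for one-class methods: standardize with
# target-train statistics and return the pieces every variant needs.
fold_pieces <- function(dataset, train_idx, test_idx, scale) {
  tr_target <- dataset$features[train_idx[dataset$labels[train_idx] == "negative"], ,
                                drop = FALSE]
  te <- dataset$features[test_idx, , drop = FALSE]
  scaler <- NULL
  if (scale && nrow(tr_target) >= 2L) {
    scaler <- suppressWarnings(fit_standardizer(tr_target))
    tr_target <- standardize(scaler, tr_target)
    te <- standardize(scaler, te)
  }
  list(train = tr_target, test = te, test_labels = dataset$labels[test_idx])
}

eval_scores <- function(test_labels, scores, theta) {
  # higher score = less target-like = more positive-like
  pred <- ifelse(scores < theta, "negative", "positive")
  cts <- confusion(test_labels, pred, positive = "positive")
  compute_metrics(cts, auc = auc_score(test_labels, scores))
}

#' Run an OCNN experiment
#'
#' Executes the repeated stratified CV protocol for the OCNN variants.
#' Per fold: target-class training rows are kept; for the tuned variants a
#' proxy dataset is built (IQR detector for the plain variants, KMOR for
#' the `_kmor` variants), `(J, K)` is grid-searched with `theta = 1`
#' (`"JKNN"`, `"JKNN_kmor"`) or `theta` is scanned (`"11NN_theta"`,
#' `"11NN_theta_kmor"`); the fitted model is evaluated on the mixed test
#' fold.  `"11NN"` uses `J = K = theta = 1` with no tuning.
#'
#' @param dataset A [labeled_dataset()] with both classes.
#' @param config An [experiment_config()] whose method is an OCNN variant.
#' @return A `run_record`.
#' @export
run_ocnn_experiment <- function(dataset, config = experiment_config("JKNN")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  method <- config$method
  if (!method %in% c("11NN", "11NN_theta", "JKNN", "11NN_theta_kmor",
                     "JKNN_kmor")) {
    stop("run_ocnn_experiment handles the OCNN variants only", call. = FALSE)
  }
  detector <- if (grepl("kmor", method)) "kmor" else "iqr"

  run_protocol(dataset, config, function(train_idx, test_idx, fold_seed) {
    p <- fold_pieces(dataset, train_idx, test_idx, config$scale)
    if (nrow(p$train) < 4L) return(NULL)

    J <- 1L; K <- 1L; theta <- 1
    if (method != "11NN") {
      proxy <- withCallingHandlers(
        build_proxy_dataset(p$train, method = detector,
                            kmor_config = config$kmor,
                            k_candidates = config$k_candidates),
        warning = function(w) invokeRestart("muffleWarning"))
      if (method %in% c("JKNN", "JKNN_kmor")) {
        jk <- suppressWarnings(
          optimize_jk(proxy, config$J_values, config$K_values,
                      inner_folds = config$inner_folds, seed = fold_seed))
        J <- jk$J_best; K <- jk$K_best
      } else {
        sc <- suppressWarnings(
          optimize_theta(proxy, inner_folds = config$inner_folds,
                         seed = fold_seed,
                         theta_fallback = config$theta_fallback))
        theta <- sc$theta_best
      }
    }
    if (nrow(p$train) < J + K) return(NULL)
    model <- ocnn_fit(p$train, J = J, K = K, theta = theta, scale = FALSE)
    eval_scores(p$test_labels, ocnn_score(model, p$test), theta)
  })
}

#' Run an LBNN experiment
#'
#' Same outer protocol as [run_ocnn_experiment()], fitting an LBNN model
#' (KMOR clustering with cluster-count selection, percentile rank `Q`) on
#' the target-class training rows of each fold.
#'
#' @inheritParams run_ocnn_experiment
#' @return A `run_record`.
#' @export
run_lbnn_experiment <- function(dataset, config = experiment_config("LBNN")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  run_protocol(dataset, config, function(train_idx, test_idx, fold_seed) {
    p <- fold_pieces(dataset, train_idx, test_idx, config$scale)
    if (nrow(p$train) < 4L) return(NULL)
    cfg <- config$kmor
    cfg$seed <- fold_seed
    model <- lbnn_fit(p$train, Q = config$Q,
                      k_candidates = config$k_candidates,
                      kmor_config = cfg, scale = FALSE)
    eval_scores(p$test_labels, lbnn_score(model, p$test), theta = 1)
  })
}

#' Run a wrapped baseline experiment
#'
#' Wraps existing implementations under the identical split protocol:
#' one-class SVM (`e1071::svm`, `nu = 0.5`, RBF kernel with coefficient
#' `1/d`, fitted on target rows only), logistic regression (`stats::glm`),
#' SVM with RBF kernel (`e1071::svm`) and random forest
#' (`randomForest::randomForest`); the binary baselines train on both
#' classes.  These are wrapped, not re-implemented; a missing optional
#' dependency skips the run with a warning and returns `NULL`.
#'
#' @inheritParams run_ocnn_experiment
#' @return A `run_record`, or `NULL` when the backing package is absent.
#' @export
run_baselines <- function(dataset, config = experiment_config("OCSVM")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  method <- config$method
  if (!method %in% c("OCSVM", "LR", "SVM", "RF")) {
    stop("run_baselines handles OCSVM, LR, SVM and RF only", call. = FALSE)
  }
  pkg <- switch(method, OCSVM = "e1071", SVM = "e1071", RF = "randomForest",
                LR = NULL)
  if (!is.null(pkg) && !requireNamespace(pkg, quietly = TRUE)) {
    warning(sprintf("package '%s' not available: %s baseline skipped",
                    pkg, method))
    return(NULL)
  }
  d <- ncol(dataset$features)

  run_protocol(dataset, config, function(train_idx, test_idx, fold_seed) {
    Xtr <- dataset$features[train_idx, , drop = FALSE]
    ytr <- dataset$labels[train_idx]
    Xte <- dataset$features[test_idx, , drop = FALSE]
    yte <- dataset$labels[test_idx]
    scaler <- suppressWarnings(fit_standardizer(Xtr))
    Xtr <- standardize(scaler, Xtr); Xte <- standardize(scaler, Xte)

    scores <- with_seed(fold_seed, switch(method,
      OCSVM = {
        fit <- e1071::svm(Xtr[ytr == "negative", , drop = FALSE],
                          type = "one-classification", nu = 0.5, gamma = 1 / d)
        dv <- attr(predict(fit, Xte, decision.values = TRUE), "decision.values")
        -as.numeric(dv)           # below the hyperplane = more outlier-like
      },
      LR = {
        df <- data.frame(Xtr, y = as.integer(ytr == "positive"))
        fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
        as.numeric(predict(fit, newdata = data.frame(Xte), type = "response"))
      },
      SVM = {
        fit <- e1071::svm(Xtr, factor(ytr, c("negative", "positive")),
                          kernel = "radial", probability = TRUE)
        pr <- attr(predict(fit, Xte, probability = TRUE), "probabilities")
        as.numeric(pr[, "positive"])
      },
      RF = {
        fit <- randomForest::randomForest(Xtr, factor(ytr, c("negative", "positive")))
        as.numeric(predict(fit, Xte, type = "prob")[, "positive"])
      }))
    thr <- if (method == "OCSVM") 0 else 0.5
    pred <- ifelse(scores > thr, "positive", "negative")
    cts <- confusion(yte, pred, positive = "positive")
    compute_metrics(cts, auc = auc_score(yte, scores))
  })
}
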