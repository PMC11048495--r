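# Parameter optimization from one-class data alone.
#
# No non-target data is available at training time, so tuning manufactures a
# stand-in: outliers detected inside the target class (by an IQR fence on
# nearest-neighbor distances, or by KMOR) are relabeled as proxy non-targets,
# and (J, K) / theta are chosen by cross-validated G-means on the resulting
# binary "proxy dataset".

#' Interquartile-range outlier detection on nearest-neighbor distances
#'
#' Computes each point's Euclidean distance to its nearest neighbor (self
#' excluded) and flags points whose distance exceeds `Q3 + 1.5 * IQR` of the
#' distance distribution (quartiles by linear interpolation).  Distance-based
#' fences are multivariate-safe, unlike per-feature fences which flag
#' marginal extremes that may be ordinary in joint distance.  Note the
#' detector is blind to tight pairs of outliers: two coincident far points
#' are each other's nearest neighbor at distance 0 and neither is flagged.
#'
#' @param X Numeric matrix with at least 4 rows.
#' @return Integer vector of flagged row indices.
#' @export
iqr_outliers <- function(X) {
  X <- as_matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 points for IQR fences", call. = FALSE)
  dmat <- sqrt(pairwise_sqdist(X, X))
  diag(dmat) <- Inf
  nn1 <- apply(dmat, 1L, min)
  q <- stats::quantile(nn1, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  which(nn1 > fence)
}

#' Build a proxy dataset from target-class data
#'
#' Runs an outlier detector on the target-class training matrix and labels
#' detected points `"proxy-outlier"`, the rest `"target"`.  If no outlier is
#' detected the all-target dataset is returned with a warning (parameter
#' optimization then falls back to defaults).
#'
#' @param target_X Numeric matrix of target-class data.
#' @param method `"iqr"` or `"kmor"`.
#' @param kmor_config A [kmor_config()] used when `method = "kmor"`.
#' @param k_candidates Candidate cluster counts for the KMOR detector; the
#'   count is chosen by [kmor_select_k()].
#' @return Object of class `proxy_dataset` with fields `features`,
#'   `proxy_labels`, `source`.
#' @export
build_proxy_dataset <- function(target_X, method = c("iqr", "kmor"),
                                kmor_config = oclab::kmor_config(),
                                k_candidates = 1:3) {
  method <- match.arg(method)
  target_X <- as_matrix(target_X, "target_X")
  out_idx <- if (method == "iqr") {
    iqr_outliers(target_X)
  } else {
    sel <- kmor_select_k(target_X, k_candidates, kmor_config)
    sel$results[[as.character(sel$k_best)]]$outlier_indices
  }
  labels <- rep("target", nrow(target_X))
  labels[out_idx] <- "proxy-outlier"
  if (!length(out_idx)) {
    warning("no outliers detected: proxy dataset is all-target")
  }
  structure(list(features = target_X, proxy_labels = labels, source = method),
            class = "proxy_dataset")
}

proxy_fold_sets <- function(proxy, inner_folds, seed) {
  folds_id <- stratified_folds(proxy$proxy_labels, inner_folds, seed)
  lapply(sort(unique(folds_id)), function(f) {
    tr <- which(folds_id != f)
    list(train_target = tr[proxy$proxy_labels[tr] == "target"],
         val = which(folds_id == f))
  })
}

proxy_gmeans <- function(y_true, accepted) {
  pred <- ifelse(accepted, "target", "proxy-outlier")
  cts <- confusion(y_true, pred, positive = "proxy-outlier")
  rec <- safe_ratio(cts$TP, cts$TP + cts$FN)
  spec <- safe_ratio(cts$TN, cts$TN + cts$FP)
  if (is.na(rec) || is.na(spec)) NA_real_ else gmeans(rec, spec)
}

#' Optimize the neighbor counts (J, K) on a proxy dataset
#'
#' Grid search: for each (J, K), a stratified inner cross-validation fits a
#' JKNN model with `theta = 1` on the target-labeled part of each training
#' fold and classifies the held-out mix; the cell score is the mean G-means
#' across folds (positive class = proxy-outlier).  Cells whose `J + K`
#' exceeds a fold's target training size are scored `NA` and excluded.
#' Ties are broken toward the smallest `J`, then the smallest `K`.
#'
#' @param proxy A [build_proxy_dataset()] result with both labels present.
#' @param J_values,K_values Candidate integer grids (default `1:10`).
#' @param inner_folds Number of inner CV folds (default 2).
#' @param seed Integer seed fixing the fold assignment.
#' @return List with `J_best`, `K_best` and `grid` (a `jk_grid` object with
#'   `J_values`, `K_values`, `score_matrix`).
#' @export
optimize_jk <- function(proxy, J_values = 1:10, K_values = 1:10,
                        inner_folds = 2L, seed = 1L) {
  stopifnot(inherits(proxy, "proxy_dataset"))
  if (!any(proxy$proxy_labels == "proxy-outlier")) {
    warning("proxy dataset has no proxy-outliers: returning J = K = 1")
    grid <- structure(list(J_values = J_values, K_values = K_values,
                           score_matrix = matrix(NA_real_, length(J_values),
                                                 length(K_values))),
                      class = "jk_grid")
    return(list(J_best = 1L, K_best = 1L, grid = grid))
  }
  sets <- proxy_fold_sets(proxy, inner_folds, seed)
  X <- proxy$features
  score <- matrix(NA_real_, length(J_values), length(K_values),
                  dimnames = list(J_values, K_values))
  for (ji in seq_along(J_values)) {
    for (ki in seq_along(K_values)) {
      J <- J_values[ji]; K <- K_values[ki]
      if (any(vapply(sets, function(s) length(s$train_target), 0L) < J + K)) {
        next  # cell unfittable in some fold: left NA, excluded from argmax
      }
      g <- vapply(sets, function(s) {
        model <- ocnn_fit(X[s$train_target, , drop = FALSE],
                          J = J, K = K, theta = 1)
        acc <- ocnn_classify(model, X[s$val, , drop = FALSE]) == "target"
        proxy_gmeans(proxy$proxy_labels[s$val], acc)
      }, numeric(1))
      score[ji, ki] <- mean(g, na.rm = TRUE)
    }
  }
  if (all(is.na(score))) {
    warning("no (J, K) cell could be evaluated: returning J = K = 1")
    best <- c(1L, 1L)
  } else {
    # row-major scan with strict improvement => smallest J then K on ties
    best <- c(J_values[1], K_values[1]); best_score <- -Inf
    for (ji in seq_along(J_values)) {
      for (ki in seq_along(K_values)) {
        if (!is.na(score[ji, ki]) && score[ji, ki] > best_score) {
          best_score <- score[ji, ki]
          best <- c(J_values[ji], K_values[ki])
        }
      }
    }
  }
  grid <- structure(list(J_values = J_values, K_values = K_values,
                         score_matrix = score),
                    class = "jk_grid")
  list(J_best = as.integer(best[1]), K_best = as.integer(best[2]), grid = grid)
}

#' Optimize the acceptance threshold theta on a proxy dataset
#'
#' For every validation point across the inner folds, computes the candidate
#' ratio `D1 / D11`: its distance to the nearest target-only training point,
#' divided by that neighbor's own nearest-neighbor distance within the
#' training part (self excluded).  Candidates with `D11 = 0` are skipped.
#' Each pooled candidate is then evaluated as the threshold of an 11NN
#' classifier under the same cross-validation, scoring G-means over the
#' pooled validation decisions; the best candidate wins, ties going to the
#' smallest theta.  If no candidate can be formed, `theta_fallback` is
#' returned with a warning.
#'
#' @inheritParams optimize_jk
#' @param theta_fallback Threshold returned when the scan is degenerate
#'   (default 1.5).
#' @return Object of class `theta_scan`: `candidates`,
#'   `gmeans_by_candidate`, `theta_best`, plus per-point `point_scores` and
#'   `point_labels` for diagnostics.
#' @export
optimize_theta <- function(proxy, inner_folds = 2L, seed = 1L,
                           theta_fallback = 1.5) {
  stopifnot(inherits(proxy, "proxy_dataset"))
  has_proxy <- any(proxy$proxy_labels == "proxy-outlier")
  if (!has_proxy) {
    warning("proxy dataset has no proxy-outliers: returning fallback theta")
    return(structure(list(candidates = numeric(0),
                          gmeans_by_candidate = numeric(0),
                          theta_best = theta_fallback,
                          point_scores = numeric(0),
                          point_labels = character(0)),
                     class = "theta_scan"))
  }
  sets <- proxy_fold_sets(proxy, inner_folds, seed)
  X <- proxy$features

  point_scores <- numeric(0)
  point_labels <- character(0)
  candidates <- numeric(0)
  for (s in sets) {
    tr <- X[s$train_target, , drop = FALSE]
    if (nrow(tr) < 2L) next
    # each training point's own nearest-neighbor distance (self excluded)
    dtr <- sqrt(pairwise_sqdist(tr, tr))
    diag(dtr) <- Inf
    d11 <- apply(dtr, 1L, min)
    for (v in s$val) {
      d <- point_dist(tr, X[v, ])
      j1 <- which.min(d)
      D1 <- d[j1]
      score <- if (D1 == 0) 0 else if (d11[j1] == 0) Inf else D1 / d11[j1]
      point_scores <- c(point_scores, score)
      point_labels <- c(point_labels, proxy$proxy_labels[v])
      if (is.finite(score) && score > 0) candidates <- c(candidates, score)
    }
  }
  if (!length(candidates)) {
    warning("theta scan degenerate (no finite D1/D11 ratios): using fallback")
    return(structure(list(candidates = numeric(0),
                          gmeans_by_candidate = numeric(0),
                          theta_best = theta_fallback,
                          point_scores = point_scores,
                          point_labels = point_labels),
                     class = "theta_scan"))
  }
  g <- vapply(candidates, function(th) {
    proxy_gmeans(point_labels, point_scores < th)
  }, numeric(1))
  ok <- !is.na(g)
  best <- which(ok & g == max(g[ok]))
  theta_best <- min(candidates[best])  # ties -> smallest theta
  structure(list(candidates = candidates, gmeans_by_candidate = g,
                 theta_best = theta_best,
                 point_scores = point_scores, point_labels = point_labels),
            class = "theta_scan")
}

#' @export
print.theta_scan <- function(x, ...) {
  cat(sprintf("<theta_scan> %d candidate(s), theta_best = %.6g\n",
              length(x$candidates), x$theta_best))
  invisible(x)
}
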