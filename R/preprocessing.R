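# Feature standardization for distance-based estimators, and greedy forward
# stepwise feature selection scored by cross-validated AUC.

#' Fit a feature standardizer
#'
#' Per-feature location (mean) and scale (population standard deviation,
#' ddof 0), fitted on training data only.  Constant features receive scale 1
#' with a warning so transformed values are exactly zero rather than NaN.
#'
#' @param train Numeric matrix with at least 2 rows.
#' @return Object of class `standardizer` with fields `location`, `scale`.
#' @export
fit_standardizer <- function(train) {
  train <- as_matrix(train, "train")
  if (nrow(train) < 2L) stop("need at least 2 rows to fit a standardizer",
                             call. = FALSE)
  location <- colMeans(train)
  scale <- sqrt(colMeans(sweep(train, 2, location)^2))
  if (any(scale == 0)) {
    warning(sprintf("%d constant feature(s): scale set to 1", sum(scale == 0)))
    scale[scale == 0] <- 1
  }
  structure(list(location = location, scale = scale), class = "standardizer")
}

#' Apply or invert a standardizer
#'
#' @param scaler A [fit_standardizer()] result.
#' @param X Numeric matrix with matching number of columns.
#' @return The transformed (or back-transformed) matrix.
#' @export
standardize <- function(scaler, X) {
  stopifnot(inherits(scaler, "standardizer"))
  X <- as_matrix(X)
  sweep(sweep(X, 2, scaler$location), 2, scaler$scale, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(scaler, X) {
  stopifnot(inherits(scaler, "standardizer"))
  X <- as_matrix(X)
  sweep(sweep(X, 2, scaler$scale, "*"), 2, scaler$location, "+")
}

# Default reference scorer for binary data: distance to the centroid of the
# target (negative) training class; larger distance -> more positive-like.
centroid_scorer <- function(train_X, train_y, test_X) {
  target <- train_X[train_y == "negative", , drop = FALSE]
  if (!nrow(target)) target <- train_X
  centroid <- colMeans(target)
  sqrt(rowSums(sweep(test_X, 2, centroid)^2))
}

# Cross-validated AUC of a feature subset under a scorer.
cv_subset_auc <- function(X, labels, cols, folds_id, scorer) {
  scores <- numeric(length(labels))
  for (f in sort(unique(folds_id))) {
    te <- folds_id == f
    scores[te] <- scorer(X[!te, cols, drop = FALSE], labels[!te],
                         X[te, cols, drop = FALSE])
  }
  auc_score(labels, scores)
}

#' Forward stepwise feature selection by AUC
#'
#' Greedy forward selection: each round evaluates every remaining feature
#' joined with the already-kept set via stratified K-fold cross-validation
#' of a reference scorer, keeps the feature with the best AUC (ties broken
#' toward the lowest feature index), and repeats until `n_keep` features are
#' retained.  Selection continues to `n_keep` even if the best AUC drops,
#' unless `early_stop = TRUE`.
#'
#' @param dataset A [labeled_dataset()] with both classes present.
#' @param n_keep Number of features to retain (`1 <= n_keep <= n_features`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param scorer Function `(train_X, train_y, test_X) -> scores` with larger
#'   scores meaning more positive-like; defaults to distance from the
#'   target-class centroid.
#' @param early_stop If `TRUE`, stop once the best achievable AUC decreases
#'   between rounds.
#' @return Object of class `selection_trace`: `selected` (ordered indices),
#'   `scores` (best AUC per round) and `evaluator`.
#' @export
stepwise_select <- function(dataset, n_keep, folds = 5L, seed = 1L,
                            scorer = centroid_scorer, early_stop = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$features
  p <- ncol(X)
  if (n_keep < 1L || n_keep > p) {
    stop("n_keep must lie in [1, n_features]", call. = FALSE)
  }
  if (length(unique(dataset$labels)) < 2L) {
    stop("both classes must be present for AUC-based selection", call. = FALSE)
  }
  folds_id <- stratified_folds(dataset$labels, folds, seed)

  selected <- integer(0)
  scores <- numeric(0)
  while (length(selected) < n_keep) {
    remaining <- setdiff(seq_len(p), selected)
    best_j <- NA_integer_
    best_auc <- -Inf
    for (j in remaining) {  # ascending index order => lowest-index tie-break
      a <- cv_subset_auc(X, dataset$labels, c(selected, j), folds_id, scorer)
      if (!is.na(a) && a > best_auc) {
        best_auc <- a
        best_j <- j
      }
    }
    if (early_stop && length(scores) && best_auc < scores[length(scores)]) break
    selected <- c(selected, best_j)
    scores <- c(scores, best_auc)
  }
  structure(list(selected = selected, scores = scores, evaluator = "auc"),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d feature(s): %s\n", length(x$selected),
              paste(sprintf("%d (%.3f)", x$selected, x$scores), collapse = ", ")))
  invisible(x)
}
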