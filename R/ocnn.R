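# The OCNN family of one-class nearest-neighbor classifiers.
#
# A test point z is scored by the ratio D_J / D_K, where D_J is the mean
# Euclidean distance from z to its J nearest training points and D_K is the
# mean distance from each of those J neighbors to its own K nearest training
# neighbors (the neighbor itself excluded).  z is accepted as target class
# when the ratio is below the threshold theta.  The four variants 11NN,
# 1KNN, J1NN and JKNN fix J and/or K at 1.

#' Exact k-nearest-neighbor query
#'
#' Naive exact search by Euclidean distance; ties broken toward the lowest
#' row index.
#'
#' @param X Numeric matrix of candidate rows.
#' @param query Numeric vector (one point).
#' @param m Number of neighbors requested.
#' @param exclude_index Optional row index excluded from the candidates
#'   (self-exclusion for in-sample queries).
#' @return List with `indices` (into the rows of `X`) and `distances`,
#'   both ordered by non-decreasing distance.
#' @export
knn_query <- function(X, query, m, exclude_index = NULL) {
  X <- as_matrix(X)
  d <- point_dist(X, query)
  cand <- seq_len(nrow(X))
  if (!is.null(exclude_index)) cand <- cand[cand != exclude_index]
  if (m > length(cand)) {
    stop(sprintf("m = %d exceeds the %d available rows", m, length(cand)),
         call. = FALSE)
  }
  ord <- cand[order(d[cand], method = "radix")]  # radix is stable: lowest index first
  sel <- ord[seq_len(m)]
  list(indices = sel, distances = d[sel])
}

#' Fit an OCNN model
#'
#' Stores the target-class training matrix together with the parameters
#' `J`, `K` and `theta`, and precomputes each training point's mean distance
#' to its own `K` nearest training neighbors (self excluded).
#'
#' @param train Numeric matrix of target-class training data (n x d),
#'   with `n >= J + K`.
#' @param J First-stage neighbor count (neighbors of the test point).
#' @param K Second-stage neighbor count (neighbors of those neighbors).
#' @param theta Acceptance threshold on the score `D_J / D_K` (> 0).
#' @param scale If `TRUE` (default) features are standardized using
#'   statistics of `train`; test points are transformed identically.
#' @return Object of class `ocnn_model`.
#' @export
ocnn_fit <- function(train, J = 1L, K = 1L, theta = 1, scale = TRUE) {
  train <- as_matrix(train, "train")
  J <- as.integer(J); K <- as.integer(K)
  if (J < 1L || K < 1L) stop("J and K must be >= 1", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  n <- nrow(train)
  if (n < J + K) {
    stop(sprintf("need n >= J + K training rows (n = %d, J = %d, K = %d)",
                 n, J, K), call. = FALSE)
  }
  scaler <- NULL
  if (scale && n >= 2L) {
    scaler <- suppressWarnings(fit_standardizer(train))
    train <- standardize(scaler, train)
  }
  # mean distance of each training point to its K nearest co-trainees;
  # distances by direct differencing so scores are reproducible against
  # naive summation to machine precision
  dmat <- vapply(seq_len(n), function(i) point_dist(train, train[i, ]),
                 numeric(n))
  diag(dmat) <- Inf
  dk <- apply(dmat, 1L, function(row) mean(sort(row, partial = K)[seq_len(K)]))
  structure(list(train = train, J = J, K = K, theta = theta,
                 scaler = scaler, dk = dk),
            class = "ocnn_model")
}

#' @export
print.ocnn_model <- function(x, ...) {
  cat(sprintf("<ocnn_model> %s: J=%d, K=%d, theta=%.4g, %d training rows\n",
              variant_name(x$J, x$K), x$J, x$K, x$theta, nrow(x$train)))
  invisible(x)
}

variant_name <- function(J, K) {
  if (J == 1 && K == 1) "11NN" else if (J == 1) "1KNN"
  else if (K == 1) "J1NN" else "JKNN"
}

#' OCNN score D_J / D_K
#'
#' Returns the decision ratio for each row of `Z`.  Degenerate cases follow
#' ratio semantics: `D_J = 0` (the test point coincides with a training
#' point) scores 0 and is accepted for any positive threshold; `D_K = 0`
#' with `D_J > 0` (duplicated training points) scores `Inf` and is rejected
#' for any finite threshold.
#'
#' @param model An [ocnn_fit()] result.
#' @param Z Numeric matrix of test points (rows), or a single vector.
#' @return Numeric vector of scores.
#' @export
ocnn_score <- function(model, Z) {
  stopifnot(inherits(model, "ocnn_model"))
  Z <- as_matrix(Z, "Z")
  if (ncol(Z) != ncol(model$train)) {
    stop("test data dimension does not match training data", call. = FALSE)
  }
  if (!is.null(model$scaler)) Z <- standardize(model$scaler, Z)
  n <- nrow(model$train)
  J <- model$J
  vapply(seq_len(nrow(Z)), function(i) {
    d <- point_dist(model$train, Z[i, ])
    nb <- order(d, method = "radix")[seq_len(J)]  # stable: lowest index on ties
    DJ <- mean(d[nb])
    DK <- mean(model$dk[nb])
    if (DJ == 0) 0 else if (DK == 0) Inf else DJ / DK
  }, numeric(1))
}

#' Classify test points with an OCNN model
#'
#' A point is labeled `"target"` when its score is strictly below the
#' model's `theta`, `"non-target"` otherwise.
#'
#' @inheritParams ocnn_score
#' @return Character vector of `"target"` / `"non-target"` (empty for an
#'   empty test matrix).
#' @export
ocnn_classify <- function(model, Z) {
  Z <- as_matrix(Z, "Z")
  if (nrow(Z) == 0L) return(character(0))
  ifelse(ocnn_score(model, Z) < model$theta, "target", "non-target")
}

#' OCNN variant templates
#'
#' The four named variants fix some parameters: `11NN` forces `J = K = 1`,
#' `1KNN` forces `J = 1`, `J1NN` forces `K = 1`, `JKNN` leaves both free.
#' Supplying a value that contradicts a variant's fixed parameter is an
#' error.
#'
#' @param name One of `"11NN"`, `"1KNN"`, `"J1NN"`, `"JKNN"`.
#' @param J,K Neighbor counts where the variant leaves them free.
#' @param theta Acceptance threshold.
#' @return A list template with entries `name`, `J`, `K`, `theta`, ready to
#'   be passed to [ocnn_fit()] via `do.call` after adding `train`.
#' @export
make_variant <- function(name = c("11NN", "1KNN", "J1NN", "JKNN"),
                         J = NULL, K = NULL, theta = 1) {
  name <- match.arg(name)
  fixed_err <- function(param, value) {
    stop(sprintf("variant %s fixes %s = 1 (got %s)", name, param, value),
         call. = FALSE)
  }
  if (name %in% c("11NN", "1KNN") && !is.null(J) && J != 1L) fixed_err("J", J)
  if (name %in% c("11NN", "J1NN") && !is.null(K) && K != 1L) fixed_err("K", K)
  J <- switch(name, "11NN" = 1L, "1KNN" = 1L, as.integer(J %||% 1L))
  K <- switch(name, "11NN" = 1L, "J1NN" = 1L, as.integer(K %||% 1L))
  list(name = name, J = J, K = K, theta = theta)
}
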