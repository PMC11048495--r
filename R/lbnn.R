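# Location-based nearest-neighbor (LBNN) one-class classifier.
#
# The target training data are first clustered with KMOR (outliers dropped).
# A test point is compared against each cluster through a reference point:
# its nearest member of that cluster.  The reference's distances to the
# other members of its cluster form an empirical within-cluster distance
# distribution L; the test point is accepted as target class as soon as its
# distance to some cluster's reference falls strictly below the Q-th
# percentile of that reference's L.  Unlike plain nearest-neighbor rules,
# the acceptance threshold adapts to the local cluster geometry.

#' Linear-interpolation percentile
#'
#' Percentile of rank `Q` on the sorted values: rank `r = Q * (m - 1)`,
#' linearly interpolating between the bracketing order statistics
#' (`Q = 0` gives the minimum, `Q = 1` the maximum).
#'
#' @param values Non-empty numeric vector.
#' @param Q Percentile rank in `[0, 1]`.
#' @return The interpolated percentile.
#' @export
percentile <- function(values, Q) {
  if (!length(values)) stop("percentile of an empty vector is undefined",
                            call. = FALSE)
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]", call. = FALSE)
  stats::quantile(values, probs = Q, type = 7, names = FALSE)
}

#' Fit an LBNN model
#'
#' Clusters the target-class training data with KMOR (the cluster count
#' either fixed via `k` or chosen from `k_candidates` by minimum objective),
#' drops outlier-cluster members, and stores the per-cluster member
#' matrices together with each member's acceptance threshold: the `Q`-th
#' percentile of its distances to the other members of its cluster.
#' Singleton clusters have an empty distance vector, so their member is
#' merged into the cluster with the nearest center.
#'
#' @param target_X Numeric matrix of target-class training data (>= 2 rows).
#' @param Q Percentile rank in `[0, 1]` (default 0.9).
#' @param k Fixed number of clusters, or `NULL` to select from
#'   `k_candidates`.
#' @param k_candidates Candidate cluster counts for [kmor_select_k()].
#' @param kmor_config A [kmor_config()]; its `k` field is overridden.
#' @param scale If `TRUE` (default) features are standardized with
#'   statistics of `target_X`.
#' @return Object of class `lbnn_model` with fields `clusters` (list of
#'   member matrices), `thresholds` (list of per-member percentile
#'   thresholds), `Q`, `kmor_result`, `scaler`.
#' @export
lbnn_fit <- function(target_X, Q = 0.9, k = NULL, k_candidates = 1:3,
                     kmor_config = oclab::kmor_config(), scale = TRUE) {
  target_X <- as_matrix(target_X, "target_X")
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]", call. = FALSE)
  if (nrow(target_X) < 2L) stop("need at least 2 training rows", call. = FALSE)

  scaler <- NULL
  X <- target_X
  if (scale) {
    scaler <- suppressWarnings(fit_standardizer(X))
    X <- standardize(scaler, X)
  }

  if (!is.null(k)) {
    cfg <- kmor_config
    cfg$k <- as.integer(k)
    km <- kmor_fit(X, cfg)
  } else {
    sel <- kmor_select_k(X, k_candidates, kmor_config)
    km <- sel$results[[as.character(sel$k_best)]]
  }
  k_fit <- nrow(km$centers)
  members <- lapply(seq_len(k_fit), function(j) which(km$assignments == j))
  members <- Filter(length, members)
  if (!length(members)) stop("KMOR flagged all training points as outliers",
                             call. = FALSE)

  # merge singleton clusters into the cluster with the nearest center
  sizes <- lengths(members)
  while (any(sizes == 1L) && length(members) > 1L) {
    s <- which(sizes == 1L)[1]
    pt <- X[members[[s]], , drop = FALSE]
    centers <- do.call(rbind, lapply(members, function(m) {
      colMeans(X[m, , drop = FALSE])
    }))
    d <- point_dist(centers, as.numeric(pt))
    d[s] <- Inf
    tgt <- which.min(d)
    members[[tgt]] <- c(members[[tgt]], members[[s]])
    members[[s]] <- NULL
    sizes <- lengths(members)
  }
  if (length(members) == 1L && lengths(members) < 2L) {
    stop("a single training point cannot define within-cluster distances",
         call. = FALSE)
  }

  clusters <- lapply(members, function(m) X[m, , drop = FALSE])
  thresholds <- lapply(clusters, function(C) {
    dmat <- sqrt(pairwise_sqdist(C, C))
    vapply(seq_len(nrow(C)), function(i) {
      percentile(dmat[i, -i], Q)
    }, numeric(1))
  })

  structure(list(clusters = clusters, thresholds = thresholds, Q = Q,
                 kmor_result = km, scaler = scaler),
            class = "lbnn_model")
}

#' @export
print.lbnn_model <- function(x, ...) {
  cat(sprintf("<lbnn_model> %d cluster(s) of sizes {%s}, Q = %.2f\n",
              length(x$clusters),
              paste(vapply(x$clusters, nrow, 0L), collapse = ", "), x$Q))
  invisible(x)
}

# Per-point decision detail: deciding cluster, per-cluster reference
# distance and threshold, and the count of distance evaluations performed.
lbnn_decide <- function(model, t) {
  k <- length(model$clusters)
  d_ref <- numeric(k); thr <- numeric(k); ref <- integer(k)
  n_dist <- 0L
  accepted <- 0L
  deciding <- NA_integer_
  for (c in seq_len(k)) {
    C <- model$clusters[[c]]
    d <- point_dist(C, t)
    n_dist <- n_dist + nrow(C)
    r <- which.min(d)            # ties: which.min takes the lowest index
    ref[c] <- r
    d_ref[c] <- d[r]
    thr[c] <- model$thresholds[[c]][r]
    if (accepted == 0L && d_ref[c] < thr[c]) {
      accepted <- 1L
      deciding <- c
      break                       # early break, clusters in index order
    }
  }
  scanned <- if (is.na(deciding)) k else deciding
  list(accepted = accepted, deciding_cluster = deciding,
       ref_index = ref[seq_len(scanned)], ref_distance = d_ref[seq_len(scanned)],
       threshold = thr[seq_len(scanned)], n_dist_evals = n_dist)
}

prepare_test <- function(model, Tm) {
  Tm <- as_matrix(Tm, "T")
  if (ncol(Tm) != ncol(model$clusters[[1]])) {
    stop("test data dimension does not match training data", call. = FALSE)
  }
  if (!is.null(model$scaler)) Tm <- standardize(model$scaler, Tm)
  Tm
}

#' Classify test points with an LBNN model
#'
#' Scans clusters in index order and accepts (returns 1) on the first
#' cluster whose reference distance is strictly below that reference's
#' percentile threshold; returns 0 if no cluster accepts.
#'
#' @param model An [lbnn_fit()] result.
#' @param T_ Numeric matrix of test points (rows).
#' @return Integer vector of 0/1 decisions, one per row.
#' @export
lbnn_classify <- function(model, T_) {
  stopifnot(inherits(model, "lbnn_model"))
  Tm <- prepare_test(model, T_)
  vapply(seq_len(nrow(Tm)), function(i) {
    lbnn_decide(model, Tm[i, ])$accepted
  }, integer(1))
}

#' Continuous LBNN score
#'
#' The minimum over clusters of `reference distance / percentile threshold`
#' (a threshold of 0 with positive distance scores `Inf`).  Scores below 1
#' correspond exactly to the decisions of [lbnn_classify()]: the hard rule
#' accepts if and only if some cluster's ratio is below 1.
#'
#' @inheritParams lbnn_classify
#' @return Numeric vector of scores (lower = more target-like).
#' @export
lbnn_score <- function(model, T_) {
  stopifnot(inherits(model, "lbnn_model"))
  Tm <- prepare_test(model, T_)
  vapply(seq_len(nrow(Tm)), function(i) {
    t <- Tm[i, ]
    ratios <- vapply(seq_along(model$clusters), function(c) {
      C <- model$clusters[[c]]
      d <- point_dist(C, t)
      r <- which.min(d)
      thr <- model$thresholds[[c]][r]
      if (thr > 0) d[r] / thr else Inf  # degenerate threshold: never accepts
    }, numeric(1))
    min(ratios)
  }, numeric(1))
}
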