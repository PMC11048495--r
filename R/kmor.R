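# K-means with outlier removal (KMOR).
#
# Standard K-means is fragile to outliers: a single far point drags a center
# toward it.  KMOR adds a (k+1)-th "outlier cluster" whose members are
# excluded from center updates.  A point is an outlier when its squared
# distance to the nearest center exceeds the dynamic threshold
#   D(U, Z) = gamma * (sum of non-outlier squared distances) / (n - n_out),
# i.e. gamma times the current mean non-outlier squared distance, and the
# outlier count is capped at n0.  The objective minimized is
#   P(U, Z) = sum_{non-outliers} ||x_i - z_{a_i}||^2 + n_out * D(U, Z).

#' KMOR configuration
#'
#' @param k Number of clusters (>= 1).
#' @param gamma Weight of the mean non-outlier squared distance in the
#'   outlier threshold; larger values flag fewer outliers.  Default 2.5,
#'   the value used throughout the package's reference experiments.
#' @param n0_fraction Maximum fraction of points that may be declared
#'   outliers; `n0 = floor(n0_fraction * n)`.  Must lie in `[0, 1)`.
#' @param delta Absolute convergence tolerance on the objective.
#' @param itermax Maximum number of update iterations.
#' @param seed Integer seed for the random initialization.
#' @param n_restarts Number of random restarts used by [kmor_select_k()].
#'
#' @return Object of class `kmor_config`.
#' @export
kmor_config <- function(k = 1L, gamma = 2.5, n0_fraction = 0.05,
                        delta = 1e-6, itermax = 100L, seed = 1L,
                        n_restarts = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (n0_fraction < 0 || n0_fraction >= 1) {
    stop("n0_fraction must lie in [0, 1): at least one inlier must remain",
         call. = FALSE)
  }
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (itermax < 1L) stop("itermax must be >= 1", call. = FALSE)
  structure(list(k = k, gamma = gamma, n0_fraction = n0_fraction,
                 delta = delta, itermax = as.integer(itermax),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "kmor_config")
}

#' KMOR objective P(U, Z)
#'
#' Sum of squared Euclidean distances of non-outliers to their assigned
#' centers, plus `n_out * D(U, Z)` for the outlier-cluster members, where
#' `D(U, Z)` is `gamma` times the mean non-outlier squared distance.
#'
#' @param X Numeric data matrix (n x d).
#' @param assignments Integer vector in `1..(k+1)`; `k + 1` marks outliers.
#' @param centers Numeric matrix (k x d).
#' @param gamma Positive weight in `D(U, Z)`.
#' @return The objective value.
#' @export
kmor_objective <- function(X, assignments, centers, gamma) {
  X <- as_matrix(X)
  centers <- as_matrix(centers, "centers")
  k <- nrow(centers)
  n <- nrow(X)
  stopifnot(length(assignments) == n)
  if (any(assignments < 1L | assignments > k + 1L)) {
    stop("assignments must lie in 1..(k+1)", call. = FALSE)
  }
  out <- assignments == k + 1L
  n_out <- sum(out)
  if (n_out == n) {
    stop("all points assigned to the outlier cluster: D(U, Z) undefined",
         call. = FALSE)
  }
  inl <- which(!out)
  S <- sum((X[inl, , drop = FALSE] - centers[assignments[inl], , drop = FALSE])^2)
  D <- gamma * S / (n - n_out)
  S + n_out * D
}

#' Fit KMOR
#'
#' Alternates the two update rules until the objective changes by less than
#' `delta` or `itermax` iterations are reached:
#' * Rule 1 -- recompute `D(U, Z)` from the current assignment, assign each
#'   point to its nearest center, and move the farthest points to the
#'   outlier cluster.  The outlier count `m <= n0` is chosen to minimize
#'   the objective given the current centers, which coincides with the
#'   threshold test "outlier iff nearest squared distance exceeds
#'   `D(U, Z)`" away from the decision boundary but, unlike the raw
#'   threshold test, guarantees the objective never increases (the raw test
#'   can oscillate on boundary points; see the methods vignette).
#' * Rule 2 -- each center becomes the mean of its member points, outliers
#'   excluded.  A cluster left empty is re-seeded with the farthest current
#'   non-outlier point from its assigned center.
#'
#' Initialization selects `k` distinct rows uniformly at random (seeded) and
#' assigns every point to its nearest center with no outliers, so the first
#' `D(U, Z)` is computed from an outlier-free assignment.
#'
#' @param X Numeric matrix (n x d), `n >= k`.
#' @param config A [kmor_config()].
#' @param init_centers Optional k x d matrix of starting centers, overriding
#'   the random initialization (used for reproducible comparisons).
#' @return Object of class `kmor_result` with fields `assignments`
#'   (values `1..k+1`), `centers`, `objective_trace`, `n_iterations`,
#'   `outlier_indices`, `d_threshold_final` (squared-distance units) and
#'   `cap_applied` (`TRUE` when the n0 cap truncated Rule 1's outlier set in
#'   the final iteration).
#' @export
kmor_fit <- function(X, config = kmor_config(), init_centers = NULL) {
  X <- as_matrix(X)
  n <- nrow(X)
  k <- config$k
  if (k > n) stop("k must not exceed the number of points", call. = FALSE)
  n0 <- floor(config$n0_fraction * n)

  if (is.null(init_centers)) {
    centers <- with_seed(config$seed, X[sample.int(n, k), , drop = FALSE])
  } else {
    centers <- as_matrix(init_centers, "init_centers")
    stopifnot(nrow(centers) == k, ncol(centers) == ncol(X))
  }

  D2 <- pairwise_sqdist(X, centers)
  a <- max.col(-D2, ties.method = "first")

  trace <- numeric(0)
  p_prev <- 0
  d_thr <- NA_real_
  cap_applied <- FALSE

  for (s in seq_len(config$itermax)) {
    # threshold from the current assignment and centers
    out <- a == k + 1L
    inl <- which(!out)
    S <- sum((X[inl, , drop = FALSE] - centers[a[inl], , drop = FALSE])^2)
    d_thr <- config$gamma * S / (n - sum(out))

    # Rule 1, in its descent-guaranteed form: candidate outliers are the
    # farthest points, and the outlier count m <= n0 is the one minimizing
    # P given the current centers.  The literal threshold test (outlier iff
    # dmin > D) agrees with this up to the discrete boundary, where it can
    # oscillate and raise the objective; the exact minimization cannot.
    D2 <- pairwise_sqdist(X, centers)
    nearest <- max.col(-D2, ties.method = "first")
    dmin <- D2[cbind(seq_len(n), nearest)]
    cap_applied <- sum(dmin > d_thr) > n0
    ord <- order(dmin, decreasing = TRUE)
    S0 <- sum(dmin)
    m_grid <- 0:n0
    S_m <- S0 - c(0, cumsum(dmin[ord])[seq_len(n0)])
    P_m <- S_m * (1 + config$gamma * m_grid / (n - m_grid))
    m_star <- m_grid[which.min(P_m)]   # ties -> fewest outliers
    a <- nearest
    if (m_star > 0) a[ord[seq_len(m_star)]] <- k + 1L

    # Rule 2
    for (j in seq_len(k)) {
      members <- which(a == j)
      if (length(members)) {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # empty-cluster repair: re-seed with the farthest non-outlier point
        inl2 <- which(a <= k)
        d_cur <- rowSums((X[inl2, , drop = FALSE] -
                            centers[a[inl2], , drop = FALSE])^2)
        far <- inl2[which.max(d_cur)]
        centers[j, ] <- X[far, ]
        a[far] <- j
      }
    }

    p <- kmor_objective(X, a, centers, config$gamma)
    trace <- c(trace, p)
    if (abs(p - p_prev) < config$delta) break
    p_prev <- p
  }

  structure(
    list(assignments = a, centers = centers, objective_trace = trace,
         n_iterations = length(trace),
         outlier_indices = which(a == k + 1L),
         d_threshold_final = d_thr,
         cap_applied = cap_applied,
         n0 = n0, config = config),
    class = "kmor_result"
  )
}

#' @export
print.kmor_result <- function(x, ...) {
  cat(sprintf("<kmor_result> k=%d, %d iterations, objective %.6g, %d outlier(s) (cap %d)\n",
              nrow(x$centers), x$n_iterations,
              x$objective_trace[length(x$objective_trace)],
              length(x$outlier_indices), x$n0))
  invisible(x)
}

#' Select the number of clusters by minimum objective
#'
#' Fits each candidate `k` with `config$n_restarts` random initializations
#' (restart seeds derived from `config$seed`), keeps each candidate's
#' best-objective run, and returns the candidate with the smallest final
#' objective (ties broken toward the smallest `k`).  Because the objective
#' typically decreases as `k` grows, the candidate list bounds the search;
#' the full objective-vs-k curve is returned so the choice can be inspected.
#'
#' @param X Numeric matrix.
#' @param k_candidates Non-empty integer vector of candidate cluster counts.
#' @param config A [kmor_config()]; its `k` field is ignored.
#' @return List with `k_best`, `results` (named list of `kmor_result`, one
#'   per candidate) and `objectives` (named numeric vector).
#' @export
kmor_select_k <- function(X, k_candidates, config = kmor_config()) {
  X <- as_matrix(X)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (!length(k_candidates)) stop("k_candidates must be non-empty", call. = FALSE)
  if (any(k_candidates > nrow(X))) {
    stop("all k candidates must be <= number of points", call. = FALSE)
  }
  results <- list()
  objectives <- numeric(0)
  for (k in k_candidates) {
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      cfg <- config
      cfg$k <- k
      cfg$seed <- derive_seed(config$seed, k * 1000L + r)
      fit <- kmor_fit(X, cfg)
      obj <- fit$objective_trace[length(fit$objective_trace)]
      if (is.null(best) || obj < best$objective_trace[length(best$objective_trace)]) {
        best <- fit
      }
    }
    results[[as.character(k)]] <- best
    objectives[as.character(k)] <-
      best$objective_trace[length(best$objective_trace)]
  }
  k_best <- k_candidates[which.min(objectives)]  # ties -> smallest k
  list(k_best = k_best, results = results, objectives = objectives)
}

#' Detect outliers with KMOR
#'
#' Convenience wrapper returning the outlier indices of a single
#' [kmor_fit()] run.
#'
#' @inheritParams kmor_fit
#' @return Integer vector of outlier row indices (possibly empty).
#' @export
kmor_outliers <- function(X, config = kmor_config()) {
  kmor_fit(X, config)$outlier_indices
}
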