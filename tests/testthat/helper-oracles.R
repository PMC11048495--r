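# Independent brute-force oracles.  Each re-derives a quantity by the most
# naive route available (loops, enumeration, pair counting) so the vectorized
# implementations are checked against arithmetic they do not share.

# m nearest neighbors of `q` among the rows of X, by explicit loops.
brute_knn <- function(X, q, m, exclude = NULL) {
  d <- apply(X, 1, function(r) sqrt(sum((r - q)^2)))
  cand <- setdiff(seq_len(nrow(X)), exclude)
  ord <- cand[order(d[cand])]
  ord[seq_len(m)]
}

# OCNN D_J / D_K score by explicit enumeration of both neighbor stages.
brute_ocnn_score <- function(train, z, J, K) {
  d <- apply(train, 1, function(r) sqrt(sum((r - z)^2)))
  nb <- order(d)[seq_len(J)]
  DJ <- mean(d[nb])
  dk <- vapply(nb, function(i) {
    di <- apply(train, 1, function(r) sqrt(sum((r - train[i, ])^2)))
    di[i] <- Inf
    mean(sort(di)[seq_len(K)])
  }, numeric(1))
  DK <- mean(dk)
  if (DJ == 0) 0 else if (DK == 0) Inf else DJ / DK
}

# KMOR objective by per-point loop summation (different order of operations
# than the implementation's matrix algebra).
brute_kmor_objective <- function(X, assignments, centers, gamma) {
  n <- nrow(X); k <- nrow(centers)
  S <- 0; n_out <- 0
  for (i in seq_len(n)) {
    if (assignments[i] == k + 1) n_out <- n_out + 1
    else S <- S + sum((X[i, ] - centers[assignments[i], ])^2)
  }
  S + n_out * gamma * S / (n - n_out)
}

# Independent Lloyd's K-means sharing only the documented conventions
# (nearest center, lowest-index ties, farthest-point empty-cluster repair).
lloyd_kmeans <- function(X, centers, itermax = 100, delta = 1e-6) {
  n <- nrow(X); k <- nrow(centers)
  assign_history <- list()
  p_prev <- 0
  for (s in seq_len(itermax)) {
    a <- integer(n)
    for (i in seq_len(n)) {
      di <- apply(centers, 1, function(z) sum((X[i, ] - z)^2))
      a[i] <- which.min(di)
    }
    for (j in seq_len(k)) {
      mem <- which(a == j)
      if (length(mem)) {
        centers[j, ] <- colMeans(X[mem, , drop = FALSE])
      } else {
        dcur <- vapply(seq_len(n), function(i) sum((X[i, ] - centers[a[i], ])^2),
                       numeric(1))
        far <- which.max(dcur)
        centers[j, ] <- X[far, ]
        a[far] <- j
      }
    }
    assign_history[[s]] <- a
    p <- sum(vapply(seq_len(n), function(i) sum((X[i, ] - centers[a[i], ])^2),
                    numeric(1)))
    if (abs(p - p_prev) < delta) break
    p_prev <- p
  }
  list(assignments = a, centers = centers, history = assign_history)
}

# Exhaustive KMOR optimum for tiny 1-D instances: enumerate every assignment
# of n points to k clusters plus at most n0 outliers; centers are the
# implied cluster means.
enumerate_kmor_optimum <- function(x, k, gamma, n0) {
  n <- length(x)
  best <- NULL
  labs <- c(seq_len(k), k + 1L)
  grid <- do.call(expand.grid, rep(list(labs), n))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (sum(a == k + 1L) > n0) next
    if (sum(a == k + 1L) == n) next
    if (any(vapply(seq_len(k), function(j) sum(a == j) == 0, TRUE))) next
    centers <- vapply(seq_len(k), function(j) mean(x[a == j]), numeric(1))
    S <- sum((x[a <= k] - centers[a[a <= k]])^2)
    n_out <- sum(a == k + 1L)
    P <- S + n_out * gamma * S / (n - n_out)
    if (is.null(best) || P < best$P) {
      best <- list(P = P, assignments = a, centers = sort(centers),
                   outliers = which(a == k + 1L))
    }
  }
  best
}

# AUC by O(n^2) pair counting over all positive x negative pairs.
brute_auc <- function(y, s, positive = "positive") {
  pos <- which(y == positive); neg <- which(y != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Percentile by explicit sort-and-interpolate on order statistics.
brute_percentile <- function(v, Q) {
  v <- sort(v)
  m <- length(v)
  r <- Q * (m - 1)
  lo <- floor(r) + 1
  hi <- ceiling(r) + 1
  v[lo] + (r - (lo - 1)) * (v[hi] - v[lo])
}

# Random numeric matrix helper used across property tests.
random_matrix <- function(seed, n, d, spread = 3) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d) + matrix(sample(0:spread, n * d, TRUE), n, d)
}
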