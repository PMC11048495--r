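# Seeded generator of imbalanced, clustered, outlier-contaminated datasets
# with known ground truth.  Every study condition used by the package's
# tests is a named preset of this one generator, so all constructions trace
# to a single seeded source of truth.

#' Specify a synthetic imbalanced dataset
#'
#' The target (majority, `"negative"`) class is a mixture of `n_clusters`
#' isotropic Gaussians whose centers sit on a regular simplex with pairwise
#' distance `cluster_separation * cluster_sd`.  A fraction of target points
#' are replaced by planted outliers at radius `outlier_distance * cluster_sd`
#' from their cluster center, in a random direction.  The minority
#' (`"positive"`) class is an isotropic Gaussian displaced from the centroid
#' of the cluster centers by `minority_offset * cluster_sd` along a fixed
#' direction orthogonal to the span of the centers (falling back to a
#' diagonal direction when no orthogonal direction exists).
#'
#' @param n_target Number of target-class samples.
#' @param n_minority Number of minority-class samples (may be 0 for
#'   target-only data).
#' @param n_features Dimensionality (must be >= `n_clusters` when
#'   `n_clusters > 1`).
#' @param n_clusters Number of target clusters.
#' @param cluster_sd Isotropic standard deviation of each cluster.
#' @param cluster_separation Distance between cluster centers, in units of
#'   `cluster_sd`.
#' @param outlier_fraction Fraction of target points replaced by planted
#'   outliers, in `[0, 1)`.
#' @param outlier_distance Radius of planted outliers from their cluster
#'   center, in units of `cluster_sd`.
#' @param minority_offset Displacement of the minority distribution, in
#'   units of `cluster_sd`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_target = 100L, n_minority = 0L, n_features = 2L,
                           n_clusters = 1L, cluster_sd = 1, cluster_separation = 10,
                           outlier_fraction = 0, outlier_distance = 10,
                           minority_offset = 10, seed = 1L) {
  n_target <- as.integer(n_target); n_minority <- as.integer(n_minority)
  n_features <- as.integer(n_features); n_clusters <- as.integer(n_clusters)
  if (n_target < 1L) stop("n_target must be >= 1", call. = FALSE)
  if (n_minority < 0L) stop("n_minority must be >= 0", call. = FALSE)
  if (n_clusters < 1L) stop("n_clusters must be >= 1", call. = FALSE)
  if (n_clusters > 1L && n_features < n_clusters) {
    stop("need n_features >= n_clusters to place simplex centers", call. = FALSE)
  }
  if (cluster_sd <= 0) stop("cluster_sd must be > 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_target = n_target, n_minority = n_minority,
                 n_features = n_features, n_clusters = n_clusters,
                 cluster_sd = cluster_sd, cluster_separation = cluster_separation,
                 outlier_fraction = outlier_fraction,
                 outlier_distance = outlier_distance,
                 minority_offset = minority_offset, seed = as.integer(seed)),
            class = "synthetic_spec")
}

simplex_centers <- function(c, d, edge) {
  if (c == 1L) return(matrix(0, 1L, d))
  # scaled standard-basis vectors: pairwise distance s * sqrt(2) = edge
  s <- edge / sqrt(2)
  centers <- matrix(0, c, d)
  centers[cbind(seq_len(c), seq_len(c))] <- s
  sweep(centers, 2, colMeans(centers))  # center at the origin
}

random_unit <- function(d) {
  v <- rnorm(d)
  while (sum(v^2) == 0) v <- rnorm(d)
  v / sqrt(sum(v^2))
}

minority_direction <- function(centers, d) {
  # fixed direction orthogonal to the span of the centered cluster centers
  M <- sweep(centers, 2, colMeans(centers))
  qr_M <- qr(t(M))
  rank <- qr_M$rank
  if (rank < d) {
    Qfull <- qr.Q(qr_M, complete = TRUE)
    Qfull[, d]                  # a unit vector in the null space
  } else {
    v <- rep(-1, d)
    v / sqrt(sum(v^2))
  }
}

#' Generate a synthetic dataset with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param name Dataset name recorded on the result.
#' @return List with `dataset` (a [labeled_dataset()]) and `truth`, a list
#'   holding `cluster_id` (per target row; `NA` for minority rows) and
#'   `outlier` (logical flags over all rows; planted target outliers only).
#' @export
generate_synthetic <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$n_features
  centers <- simplex_centers(spec$n_clusters, d,
                             spec$cluster_separation * spec$cluster_sd)
  with_seed(spec$seed, {
    cluster_id <- rep_len(seq_len(spec$n_clusters), spec$n_target)
    X <- centers[cluster_id, , drop = FALSE] +
      matrix(rnorm(spec$n_target * d, sd = spec$cluster_sd), spec$n_target, d)

    n_out <- floor(spec$outlier_fraction * spec$n_target)
    outlier <- rep(FALSE, spec$n_target)
    if (n_out > 0) {
      idx <- sample.int(spec$n_target, n_out)
      outlier[idx] <- TRUE
      for (i in idx) {
        X[i, ] <- centers[cluster_id[i], ] +
          spec$outlier_distance * spec$cluster_sd * random_unit(d)
      }
    }

    if (spec$n_minority > 0) {
      mu <- colMeans(centers) +
        spec$minority_offset * spec$cluster_sd * minority_direction(centers, d)
      M <- matrix(rnorm(spec$n_minority * d, sd = spec$cluster_sd),
                  spec$n_minority, d)
      M <- sweep(M, 2, mu, "+")
      X <- rbind(X, M)
      cluster_id <- c(cluster_id, rep(NA_integer_, spec$n_minority))
      outlier <- c(outlier, rep(FALSE, spec$n_minority))
    }
    labels <- c(rep("negative", spec$n_target),
                rep("positive", spec$n_minority))
    ds <- labeled_dataset(X, labels, name = name)
    list(dataset = ds, truth = list(cluster_id = cluster_id, outlier = outlier))
  })
}

#' Named synthetic presets
#'
#' The constructions used across the package's tests and examples:
#' * `"blob_with_outliers"` -- one tight Gaussian blob (sd 1) of 100 target
#'   points with 5% planted outliers at radius 10 sd; target-only.  The
#'   canonical proxy-outlier tuning construction.
#' * `"two_blobs"` -- two target clusters (sd 0.2) with centers 10 apart
#'   (separation 50 sd), target-only; the cluster-recovery construction.
#' * `"separable"` -- two target clusters (sd 1, separation 10 sd) of 250
#'   points total plus 50 minority points offset 10 sd; no planted
#'   outliers.  The end-to-end harness construction.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("blob_with_outliers", "two_blobs",
                                      "separable"),
                             seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    blob_with_outliers = list(n_target = 100L, n_minority = 0L, n_features = 2L,
                              n_clusters = 1L, cluster_sd = 1,
                              outlier_fraction = 0.05, outlier_distance = 10),
    two_blobs = list(n_target = 100L, n_minority = 0L, n_features = 2L,
                     n_clusters = 2L, cluster_sd = 0.2,
                     cluster_separation = 50, outlier_fraction = 0),
    separable = list(n_target = 250L, n_minority = 50L, n_features = 2L,
                     n_clusters = 2L, cluster_sd = 1, cluster_separation = 10,
                     outlier_fraction = 0, outlier_distance = 10,
                     minority_offset = 10)
  )
  do.call(synthetic_spec, modifyList(c(base, seed = seed), list(...)))
}
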