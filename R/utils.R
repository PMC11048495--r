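# Internal helpers shared across modules.

#' @importFrom stats quantile rnorm runif sd predict glm binomial
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points funnel
# through this so a single integer seed fixes every draw.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed; kept well below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

as_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

# Squared Euclidean distances between the rows of A (n x d) and B (m x d).
pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

# Euclidean distances from a single point to every row of X, computed by
# direct differencing (no cross-product shortcut, so values are reproducible
# against naive summation to machine precision).
point_dist <- function(X, z) {
  sqrt(colSums((t(X) - z)^2))
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin into `k` folds.  Returns an integer vector of fold ids.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2 || k > n) stop("number of folds must be in [2, n]", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
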