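#' Mini-batch k-means
#'
#' Over-clustering of window composition vectors uses mini-batch k-means with a
#' large k (default 200 downstream). This implementation follows the standard
#' mini-batch update (per-centre learning rate 1/counts) with k-means++
#' initialisation, runs `n_restarts` restarts, and keeps the run with the best
#' full-data inertia. Deterministic given `seed`.
#'
#' @param X Numeric matrix, observations in rows.
#' @param k Number of centres.
#' @param batch_size Mini-batch size.
#' @param n_iter Number of mini-batch iterations per restart.
#' @param n_restarts Restarts, best inertia kept.
#' @param seed Integer seed.
#' @return List with `cluster` (1-based assignment), `centers`, `inertia`.
#' @export
minibatch_kmeans <- function(X, k, batch_size = 1024L, n_iter = 100L,
                             n_restarts = 3L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of observations", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  xsq <- rowSums(X^2)
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp_init(X, k, xsq)
    counts <- rep(0, k)
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, min(batch_size, n))
      B <- X[idx, , drop = FALSE]
      a <- .nearest_center(B, centers)
      for (j in unique(a)) {
        rows <- idx[a == j]
        nb <- length(rows)
        counts[j] <- counts[j] + nb
        eta <- nb / counts[j]
        mu <- colMeans(X[rows, , drop = FALSE])
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * mu
      }
    }
    a <- .nearest_center(X, centers, xsq)
    inertia <- sum((X - centers[a, , drop = FALSE])^2)
    if (is.null(best) || inertia < best$inertia) {
      best <- list(cluster = a, centers = centers, inertia = inertia)
    }
  }
  best
}

.kmeanspp_init <- function(X, k, xsq = rowSums(X^2)) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- pmax(xsq - 2 * drop(X %*% X[i, ]) + sum(X[i, ]^2), 0)
  if (k > 1) {
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        i <- sample.int(n, 1)
      } else {
        i <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[i, ]
      d2i <- pmax(xsq - 2 * drop(X %*% X[i, ]) + sum(X[i, ]^2), 0)
      d2 <- pmin(d2, d2i)
    }
  }
  centers
}

.nearest_center <- function(B, centers, bsq = rowSums(B^2)) {
  # argmin_j ||b - c_j||^2 = argmin_j (||c_j||^2 - 2 b.c_j)
  G <- B %*% t(centers)
  csq <- rowSums(centers^2)
  max.col(G - matrix(csq / 2, nrow(B), length(csq), byrow = TRUE),
          ties.method = "first")
}
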