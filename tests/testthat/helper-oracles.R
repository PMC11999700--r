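# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own primitives (grid kNN, even-odd ray casting, REML)
# so each check compares two independent routes.

# k nearest neighbours by full sort, ties broken by index
brute_knn <- function(x, y, k) {
  n <- length(x)
  res <- vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ord <- order(d, seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

# connected components of the symmetric kNN graph, by repeated flood fill
brute_components <- function(x, y, k) {
  n <- length(x)
  nn <- brute_knn(x, y, min(k, n - 1))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- TRUE
  adj <- adj | t(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

# winding-number point-in-polygon (vs the package's even-odd crossing test)
winding_pip <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  vapply(seq_along(px), function(q) {
    wn <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      isleft <- (x[j] - x[i]) * (py[q] - y[i]) - (px[q] - x[i]) * (y[j] - y[i])
      if (y[i] <= py[q]) {
        if (y[j] > py[q] && isleft > 0) wn <- wn + 1
      } else {
        if (y[j] <= py[q] && isleft < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# one-way ANOVA moment estimator of the intraclass correlation
icc_anova <- function(y, g) {
  g <- factor(g)
  J <- nlevels(g); N <- length(y)
  nj <- as.vector(table(g))
  msb <- sum(nj * (tapply(y, g, mean) - mean(y))^2) / (J - 1)
  msw <- sum((y - stats::ave(y, g))^2) / (N - J)
  n0 <- (N - sum(nj^2) / N) / (J - 1)
  tau2 <- max((msb - msw) / n0, 0)
  tau2 / (tau2 + msw)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
wilcox_exact_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  if (v_obs > n * (n + 1) / 4) min(2 * p_ge, 1) else min(2 * p_le, 1)
}

# adjusted Rand index
ari <- function(a, b) {
  t <- table(a, b)
  s <- sum(choose(t, 2))
  r <- sum(choose(rowSums(t), 2))
  c <- sum(choose(colSums(t), 2))
  N <- choose(sum(t), 2)
  (s - r * c / N) / ((r + c) / 2 - r * c / N)
}

# a small tissue used by several module tests
small_tissue <- function(seed = 1, ...) {
  cfg <- synthetic_config(tissue_size = c(1200, 1200), n_islets = 3,
                          n_donors = c("nonT1D" = 1, "AA+" = 0, "T1D" = 1),
                          n_lobules = 4, seed = seed, ...)
  generate_tissue(cfg)
}

# cell table of planted-position cells with minimal metadata; ids are unique
# across calls so tables can be bound together safely
make_cells <- local({
  counter <- 0L
  function(x, y, type, donor = "D1", group = "T1D") {
    counter <<- counter + length(x)
    tibble::tibble(cell_id = sprintf("%s_c%06d", donor,
                                     counter - length(x) + seq_along(x)),
                   donor_id = donor, group = group,
                   x_um = x, y_um = y, cell_type = type)
  }
})
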