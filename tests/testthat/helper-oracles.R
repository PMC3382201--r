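# Independent brute-force oracles and fixture builders used across the suite.

# Floyd-Warshall all-pairs shortest paths on a direct-distance matrix.
floyd_warshall <- function(d) {
  n <- nrow(d)
  g <- d
  diag(g) <- 0
  for (k in seq_len(n)) {
    via <- outer(g[, k], g[k, ], `+`)
    g <- pmin(g, via)
  }
  g
}

# Triangle-enumeration clustering coefficients (normalized weights).
onnela_brute <- function(m) {
  w <- m / max(m)
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    out[i] <- 2 * s / (k * (k - 1))
  }
  out
}

gzh_brute <- function(m) {
  w <- m / max(m)
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != h && j != i && h != i) num <- num + w[i, j] * w[j, h] * w[h, i]
    }
    den <- sum(w[i, ])^2 - sum(w[i, ]^2)
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# Betweenness by geodesic membership: with continuous random weights shortest
# paths are almost surely unique, so node v lies on the i-j geodesic iff
# d(i,v) + d(v,j) == d(i,j).
betweenness_oracle <- function(m, tol = 1e-9) {
  n <- nrow(m)
  d <- ifelse(m > 0, 1 / m, Inf)
  diag(d) <- 0
  geo <- floyd_warshall(d)
  out <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.finite(geo[i, j])) next
    for (v in seq_len(n)) {
      if (v == i || v == j) next
      if (abs(geo[i, v] + geo[v, j] - geo[i, j]) < tol) out[v] <- out[v] + 1
    }
  }
  out / ((n - 1) * (n - 2) / 2)
}

# Random symmetric weighted graph with continuous weights (no ties).
random_weighted_graph <- function(n, density = 0.4) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  on <- ut & matrix(runif(n * n) < density, n, n)
  m[on] <- runif(sum(on), 0.5, 3)
  m + t(m)
}

# Block-diagonal matrix: constant `within` inside blocks, `between` outside.
make_block_matrix <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), times = sizes)
  m <- matrix(between, n, n)
  same <- outer(lab, lab, `==`)
  m[same] <- within
  diag(m) <- 0
  m
}

block_labels <- function(sizes) rep(seq_along(sizes), times = sizes)

# Planted noisy partition: within/between weight ratio `ratio`, multiplicative
# lognormal-ish noise on every present edge.
planted_noisy_blocks <- function(sizes, ratio = 4, noise_cv = 0.3) {
  m <- make_block_matrix(sizes, within = ratio, between = 1)
  n <- nrow(m)
  ut <- upper.tri(m)
  noise <- matrix(0, n, n)
  noise[ut] <- rgamma(sum(ut), shape = 1 / noise_cv^2, rate = 1 / noise_cv^2)
  noise <- noise + t(noise)
  out <- m * noise
  diag(out) <- 0
  out
}

# Small default generator configuration for fast tests.
small_config <- function(seed = 1L, ...) {
  generator_config(n_nodes = 24L, n_subjects = 6L, tree_depth = 2L,
                   base_weight = 10, edge_density = 0.6, seed = seed, ...)
}

partition_labels <- function(clusters, n) {
  lab <- integer(n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}
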