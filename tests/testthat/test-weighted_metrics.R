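triangle <- function(w12, w13, w23) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- w12; m[1, 3] <- w13; m[2, 3] <- w23
  m + t(m)
}

test_that("clustering coefficients on hand-enumerable graphs", {
  eq <- triangle(2, 2, 2)
  expect_equal(onnela_clustering(eq), rep(1, 3))
  expect_equal(gzh_clustering(eq), rep(1, 3))

  tri <- triangle(1, 2, 4)   # normalized weights 0.25, 0.5, 1
  expect_equal(onnela_clustering(tri), rep((0.25 * 0.5 * 1)^(1 / 3), 3))

  path <- matrix(0, 3, 3); path[1, 2] <- 1; path[2, 3] <- 1
  path <- path + t(path)
  expect_equal(onnela_clustering(path), rep(0, 3))
  expect_equal(gzh_clustering(path), rep(0, 3))

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(gzh_clustering(star), rep(0, 5))
})

test_that("clustering coefficients match brute-force triangle enumeration", {
  set.seed(41)
  for (r in 1:10) {
    m <- random_weighted_graph(15, density = 0.5)
    expect_lt(max(abs(onnela_clustering(m) - onnela_brute(m))), 1e-12)
    expect_lt(max(abs(gzh_clustering(m) - gzh_brute(m))), 1e-12)
    expect_true(all(onnela_clustering(m) >= 0 & onnela_clustering(m) <= 1))
    expect_true(all(gzh_clustering(m) >= 0 & gzh_clustering(m) <= 1 + 1e-12))
    # invariance under global rescaling
    expect_equal(onnela_clustering(m * 7), onnela_clustering(m))
    expect_equal(gzh_clustering(m * 7), gzh_clustering(m))
  }
})

test_that("gzh reduces to the binary clustering coefficient on 0/1 graphs", {
  set.seed(42)
  m <- (random_weighted_graph(12, density = 0.5) > 0) * 1
  binary_cc <- function(a) {
    n <- nrow(a); out <- numeric(n)
    for (i in seq_len(n)) {
      nb <- which(a[i, ] > 0); k <- length(nb)
      if (k < 2) next
      out[i] <- sum(a[nb, nb]) / (k * (k - 1))
    }
    out
  }
  expect_equal(gzh_clustering(m), binary_cc(m), tolerance = 1e-12)
})

test_that("weight-to-distance transform is reciprocal with scale equivariance", {
  m <- triangle(2, 0, 1)
  d <- weight_to_distance(m)
  expect_equal(d[1, 2], 0.5)
  expect_equal(d[1, 3], Inf)
  expect_equal(diag(d), rep(0, 3))

  set.seed(43)
  g <- random_weighted_graph(12, density = 0.4)
  geo1 <- shortest_paths_matrix(weight_to_distance(g))
  geo2 <- shortest_paths_matrix(weight_to_distance(2 * g))
  expect_equal(geo2, geo1 / 2, tolerance = 1e-12)
})

test_that("shortest paths equal the Floyd-Warshall oracle on random graphs", {
  set.seed(44)
  for (r in 1:25) {
    m <- random_weighted_graph(20, density = 0.25)
    d <- weight_to_distance(m)
    got <- shortest_paths_matrix(d)
    ref <- floyd_warshall(d)
    expect_identical(is.finite(got), is.finite(ref))
    fin <- is.finite(ref)
    expect_lt(max(abs(got[fin] - ref[fin])), 1e-12)
  }
  # trivial cases
  two <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(shortest_paths_matrix(weight_to_distance(two))[1, 2], 0.5)
  disc <- matrix(0, 3, 3); disc[1, 2] <- 1; disc <- disc + t(disc)
  expect_equal(shortest_paths_matrix(weight_to_distance(disc))[1, 3], Inf)
})

test_that("average path length excludes and counts infinite pairs", {
  all1 <- matrix(1, 3, 3); diag(all1) <- 0
  geo <- shortest_paths_matrix(all1)
  expect_equal(average_path_length(geo)$L, 1)

  # components {1,2} (one edge, d = 2) and {3}
  d <- matrix(Inf, 3, 3); diag(d) <- 0; d[1, 2] <- d[2, 1] <- 2
  apl <- average_path_length(shortest_paths_matrix(d))
  expect_equal(apl$L, 2)
  expect_equal(apl$n_infinite_pairs, 2L)

  expect_error(average_path_length(matrix(c(0, Inf, Inf, 0), 2)), "disconnected")

  # adding an edge never increases L
  set.seed(45)
  for (r in 1:10) {
    m <- random_weighted_graph(12, density = 0.4)
    base <- average_path_length(shortest_paths_matrix(weight_to_distance(m)))$L
    m2 <- m
    off <- which(upper.tri(m2) & m2 == 0)
    if (!length(off)) next
    pick <- sample(off, 1)
    m2[pick] <- 2; m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
    expect_lte(average_path_length(shortest_paths_matrix(weight_to_distance(m2)))$L,
               base + 1e-12)
  }
})

test_that("betweenness matches the geodesic-membership oracle", {
  pathg <- matrix(0, 3, 3); pathg[1, 2] <- 1; pathg[2, 3] <- 1
  pathg <- pathg + t(pathg)
  expect_equal(betweenness_centrality(pathg), c(0, 1, 0))

  comp <- matrix(1, 5, 5); diag(comp) <- 0
  expect_equal(betweenness_centrality(comp), rep(0, 5))

  set.seed(46)
  for (r in 1:15) {
    m <- random_weighted_graph(15, density = 0.35)
    expect_lt(max(abs(betweenness_centrality(m) - betweenness_oracle(m))), 1e-9)
  }
})

test_that("shuffle_null conserves the weight multiset and fixes constant matrices", {
  set.seed(47)
  m <- random_weighted_graph(20, density = 0.3)
  s <- shuffle_null(m, seed = 5)
  expect_identical(sort(s[upper.tri(s)]), sort(m[upper.tri(m)]))
  expect_identical(s, t(s))
  expect_identical(shuffle_null(m, seed = 5), s)    # seeded determinism

  const <- matrix(3, 6, 6); diag(const) <- 0
  expect_identical(shuffle_null(const, seed = 1), const)

  # shuffling typically disperses the degrees of a hierarchical matrix
  worse <- 0L
  for (r in 1:20) {
    co <- generate_cohort(small_config(seed = r))
    avg <- average_matrix(co$stack)
    v0 <- var(rowSums(avg))
    v1 <- var(rowSums(shuffle_null(avg, seed = r)))
    if (v1 > v0) worse <- worse + 1L
  }
  expect_gt(worse, 10L)
})

test_that("small-world index is exactly 1 on a constant matrix and internally consistent", {
  const <- matrix(2, 8, 8); diag(const) <- 0
  r <- small_world_index(const, n_rand = 3, seed = 1)
  expect_equal(r$gamma, 1)
  expect_equal(r$lambda, 1)
  expect_equal(r$sw_index, 1)
  expect_equal(r$sw_index, r$gamma / r$lambda, tolerance = 1e-12)

  # hierarchical weight placement lengthens shortest paths relative to the
  # weight-shuffled null (lambda > 1); sigma = gamma / lambda always
  co <- generate_cohort(generator_config(seed = 3))
  avg <- average_matrix(co$stack)
  for (ccf in c("onnela", "gzh")) {
    rep <- small_world_index(avg, n_rand = 20, seed = 2, cc_formula = ccf)
    expect_gt(rep$lambda, 1)
    expect_gt(rep$sw_index, 0)
    expect_equal(rep$sw_index, rep$gamma / rep$lambda, tolerance = 1e-12)
    expect_equal(rep$cc_formula, ccf)
  }

  # increasing the null-ensemble size barely moves sigma
  s100 <- small_world_index(avg, n_rand = 100, seed = 9)$sw_index
  s400 <- small_world_index(avg, n_rand = 400, seed = 10)$sw_index
  expect_lt(abs(s100 - s400) / s400, 0.01)
})
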