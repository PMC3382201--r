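test_that("normalized operator: symmetry, spectrum, block multiplicity", {
  m <- make_block_matrix(c(4, 4))
  l <- normalized_laplacian(m)
  expect_lt(max(abs(l - t(l))), 1e-12)
  ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1 - 1e-12 & ev < 1 + 1e-12))
  # two disconnected blocks: eigenvalue 1 with multiplicity 2
  expect_equal(sum(abs(ev - 1) < 1e-12), 2L)

  # constant complete graph: top eigenvector proportional to sqrt(degree)
  k6 <- matrix(2, 6, 6); diag(k6) <- 0
  x <- top_eigenvectors(normalized_laplacian(k6), 1)
  expect_lt(max(abs(abs(x[, 1]) - 1 / sqrt(6))), 1e-12)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_error(normalized_laplacian(iso), "isolated")
})

test_that("top eigenvectors are orthonormal and deterministic", {
  set.seed(51)
  m <- random_weighted_graph(20, density = 0.5)
  l <- normalized_laplacian(m)
  x <- top_eigenvectors(l, 5)
  expect_lt(max(abs(crossprod(x) - diag(5))), 1e-10)
  expect_identical(x, top_eigenvectors(l, 5))
  # block-diagonal 6-node, 2 blocks: rows constant within blocks up to rotation
  b <- make_block_matrix(c(3, 3))
  xb <- top_eigenvectors(normalized_laplacian(b), 2)
  for (blk in list(1:3, 4:6))
    expect_lt(max(dist(xb[blk, ])), 1e-9)
})

test_that("alignment cost: fixed point, bounds, 1-angle grid-search oracle", {
  # already one-nonzero-per-row: J = n, R ~ identity
  x <- diag(4)[, 1:2]
  x <- rbind(x, x)        # 8 rows, 2 columns, orthonormal after scaling
  x <- x / sqrt(2)
  al <- align_rotation(x)
  expect_equal(al$J, 8, tolerance = 1e-9)

  # rows at 45 degrees: optimal Givens angle pi/4, J = n
  x45 <- matrix(c(1, 1, 1, -1, 1, 1, 1, -1), 4, 2, byrow = TRUE) / 2
  al45 <- align_rotation(x45)
  expect_equal(abs(al45$theta[1]) %% (pi / 2), pi / 4, tolerance = 1e-6)
  expect_equal(al45$J, 4, tolerance = 1e-8)

  # oracle: exhaustive grid over the single angle
  set.seed(52)
  xr <- qr.Q(qr(matrix(rnorm(24), 12, 2)))
  grid <- seq(-pi / 4, pi / 4, length.out = 20001)
  jg <- vapply(grid, function(th) {
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    z <- xr %*% t(r)
    z2 <- z^2
    sum(z2 / apply(z2, 1, max))
  }, numeric(1))
  al2 <- align_rotation(xr)
  expect_lte(al2$J, min(jg) + 1e-6)
  expect_gte(al2$J, nrow(xr))     # J never below n

  expect_error(align_rotation(matrix(rnorm(20), 10, 2)), "orthonormal")
})

test_that("quality maps the cost bounds onto [0, 1]", {
  expect_equal(quality(10, 10, 4), 1)
  expect_equal(quality(40, 10, 4), 0)
  expect_equal(quality(25, 10, 4), 0.5)
  expect_error(quality(10, 10, 1), "fewer than 2")

  # perfect 2-block structure reaches q = 1
  qc <- quality_curve(make_block_matrix(c(6, 6)), c_max = 4)
  expect_equal(qc$qualities[qc$group_numbers == 2], 1, tolerance = 1e-6)
})

test_that("cluster assignment reads labels off the aligned embedding", {
  z <- rbind(c(0.9, 0), c(0, -0.8), c(0.7, 0), c(0.5, 0.5))
  expect_equal(assign_clusters(z), c(1L, 2L, 1L, 1L))  # tie goes to lowest index
})

test_that("rotation and SVD discretization recover planted partitions identically", {
  set.seed(53)
  agree <- 0L
  n_seeds <- 10L
  for (r in seq_len(n_seeds)) {
    m <- planted_noisy_blocks(c(8, 8, 8), ratio = 4)
    x <- top_eigenvectors(normalized_laplacian(m), 3)
    al <- align_rotation(x)
    lab_rot <- assign_clusters(al$Z)
    lab_svd <- as.integer(discretize_svd(x))
    truth <- block_labels(c(8, 8, 8))
    expect_equal(mclust::adjustedRandIndex(lab_rot, truth), 1)
    if (mclust::adjustedRandIndex(lab_rot, lab_svd) == 1) agree <- agree + 1L
  }
  expect_gte(agree / n_seeds, 0.9)

  # idempotence of the SVD discretization on clean structure
  x <- top_eigenvectors(normalized_laplacian(make_block_matrix(c(5, 5, 5, 5))), 4)
  l1 <- discretize_svd(x)
  expect_equal(as.integer(discretize_svd(x)), as.integer(l1))
})

test_that("recursive clustering recovers a noisy planted 2-tier hierarchy", {
  # dense hierarchical means times gamma noise: the noise degrades the deeper
  # alignments, so the selection rule settles on 2 parts per tier
  set.seed(54)
  hits <- 0L
  n_seeds <- 6L
  mu <- plant_hierarchy_means(generator_config(n_nodes = 32, tree_depth = 2,
                                               decay_ratio = 3.8))$expected_mean_matrix
  cv <- 0.35
  for (r in seq_len(n_seeds)) {
    noise <- matrix(0, 32, 32)
    ut <- upper.tri(noise)
    noise[ut] <- rgamma(sum(ut), shape = 1 / cv^2, rate = 1 / cv^2)
    w <- mu * (noise + t(noise))
    tr <- cluster_recursive(w, max_tiers = 2)
    lab <- partition_labels(clusters_at_tier(tr, min(2L, tree_n_tiers(tr))), 32)
    if (mclust::adjustedRandIndex(lab, rep(1:4, each = 8)) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("the quality floor gates splitting; uniform cliques split perfectly by design", {
  const <- matrix(1, 12, 12); diag(const) <- 0
  # any bipartition of a uniform clique aligns perfectly, so q(2) = 1:
  # the quality metric cannot flag the absence of structure by itself
  qc <- quality_curve(const, c_max = 4)
  expect_equal(qc$qualities[qc$group_numbers == 2], 1, tolerance = 1e-8)
  # an unreachable floor keeps the tree at the root
  tr <- cluster_recursive(const, max_tiers = 2, quality_floor = 1.01)
  expect_equal(length(clusters_at_tier(tr, tree_n_tiers(tr))), 1L)
})

test_that("clustering is equivariant under relabeling and rescaling", {
  set.seed(55)
  m <- planted_noisy_blocks(c(10, 10), ratio = 5)
  tr <- cluster_recursive(m, max_tiers = 1)
  lab <- partition_labels(clusters_at_tier(tr, 1), 20)

  tr_scaled <- cluster_recursive(m * 13, max_tiers = 1)
  expect_equal(partition_labels(clusters_at_tier(tr_scaled, 1), 20), lab)

  perm <- sample(20)
  tr_perm <- cluster_recursive(m[perm, perm], max_tiers = 1)
  lab_perm <- partition_labels(clusters_at_tier(tr_perm, 1), 20)
  expect_equal(mclust::adjustedRandIndex(lab_perm, lab[perm]), 1)
})

test_that("planted structure scores above its shuffled null ensemble", {
  set.seed(56)
  m <- planted_noisy_blocks(c(10, 10), ratio = 5)
  out <- null_quality_comparison(m, n_rand = 15, seed = 2, c_max = 4)
  expect_gte(out$percentile, 90)
  expect_length(out$q_null, 15L)
})
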