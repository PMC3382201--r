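#' Normalized inter-cluster connectivity matrix
#'
#' For clusters X, Y partitioning the node set, sums every connectivity
#' emanating from a node of X and terminating in a node of Y, and normalizes by
#' the total weight emanating from X. The sum runs over ordered (origin,
#' destination) node pairs, so an undirected edge inside X is counted from both
#' endpoints; this is the reading under which every row of the result sums to 1
#' (conservation of outgoing weight). The diagonal entries are the clusters'
#' self-connectivities.
#'
#' @param m symmetric non-negative connectivity matrix.
#' @param clusters list of integer vectors partitioning `1..N`.
#' @return an object of class `intercluster_matrix`: list with `clusters`, `b`
#'   (K x K, rows summing to 1 where the cluster has outgoing weight), and
#'   `zero_rows` (indices of clusters without any outgoing weight, whose rows
#'   are all zero and flagged).
#' @export
between_cluster_connectivity <- function(m, clusters) {
  m <- .validate_conn_matrix(m)
  n <- nrow(m)
  all_members <- unlist(clusters)
  if (length(all_members) != n || anyDuplicated(all_members) ||
      !setequal(all_members, seq_len(n)))
    stop("partition error: clusters must partition the node set")
  k <- length(clusters)
  ind <- matrix(0, k, n)
  for (i in seq_len(k)) ind[i, clusters[[i]]] <- 1
  wsum <- ind %*% m %*% t(ind)      # (X, Y): sum over ordered pairs i in X, j in Y
  denom <- rowSums(wsum)            # total weight emanating from X
  zero_rows <- which(denom == 0)
  b <- wsum
  pos <- denom > 0
  b[pos, ] <- wsum[pos, , drop = FALSE] / denom[pos]
  b[!pos, ] <- 0
  structure(list(clusters = clusters, b = b, zero_rows = zero_rows),
            class = "intercluster_matrix")
}

#' Inter-cluster connectivity versus tree distance
#'
#' Computes the normalized inter-cluster connectivities of the clusters at one
#' tier of a hierarchy tree, groups them by the tree distance of the cluster
#' pair, and averages within groups (each ordered cluster pair weighted
#' equally). The per-level decay is then estimated on the distances `t >= 1`
#' in two equivalent forms: `exp(-slope)` of the least-squares fit of
#' `log(mean connectivity)` against `t`, and the vector of adjacent-distance
#' ratios `mean(t) / mean(t + 1)`.
#'
#' The `t = 0` self-connectivity is reported in the profile but excluded from
#' the decay estimate: the diagonal of the normalized inter-cluster matrix
#' counts each within-cluster edge from both endpoints and pools node pairs at
#' several depths of the subtree, so it does not lie on the between-cluster
#' exponential.
#'
#' Distances whose mean connectivity is zero are dropped from the fit with a
#' warning; if fewer than two usable distances remain, the ratio is `NA`.
#'
#' @param m symmetric non-negative connectivity matrix.
#' @param tree a `cluster_tree`.
#' @param tier tier of the tree at which clusters are taken.
#' @return an object of class `tree_distance_profile`: list with `profile`
#'   (data.frame: `distance`, `mean_connectivity`, `n_pairs`), `decay_ratio`
#'   (from the log-linear fit), `adjacent_ratios`, `fit_quality` (R^2 of the
#'   fit, NA when fewer than 3 points), and `tier`.
#' @export
distance_profile <- function(m, tree, tier) {
  clusters <- clusters_at_tier(tree, tier)
  icm <- between_cluster_connectivity(m, clusters)
  k <- length(clusters)
  dists <- outer(seq_len(k), seq_len(k),
                 Vectorize(function(i, j) tree_distance(tree, tier, i, j)))
  tvals <- sort(unique(as.vector(dists)))
  prof <- data.frame(
    distance = tvals,
    mean_connectivity = vapply(tvals, function(t) mean(icm$b[dists == t]), numeric(1)),
    n_pairs = vapply(tvals, function(t) sum(dists == t), integer(1)))

  fit_rows <- prof$distance >= 1
  usable <- fit_rows & prof$mean_connectivity > 0
  if (any(fit_rows & !usable))
    warning("distance level(s) with zero mean connectivity dropped from the decay fit")
  decay <- NA_real_; r2 <- NA_real_; adj <- numeric(0)
  if (sum(usable) >= 2L) {
    d <- prof$distance[usable]; y <- log(prof$mean_connectivity[usable])
    fit <- stats::lm(y ~ d)
    decay <- exp(-unname(stats::coef(fit)[2L]))
    r2 <- if (sum(usable) >= 3L) summary(fit)$r.squared else NA_real_
    mm <- prof$mean_connectivity[usable]
    adj <- mm[-length(mm)] / mm[-1L]
    names(adj) <- sprintf("t%d/t%d", d[-length(d)], d[-1L])
  }
  structure(list(profile = prof, decay_ratio = decay, adjacent_ratios = adj,
                 fit_quality = r2, tier = tier),
            class = "tree_distance_profile")
}

#' @export
print.tree_distance_profile <- function(x, ...) {
  cat(sprintf("tree_distance_profile (tier %d): decay ratio = %s per level\n",
              x$tier, ifelse(is.na(x$decay_ratio), "NA",
                             sprintf("%.3f", x$decay_ratio))))
  print(x$profile)
  invisible(x)
}
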