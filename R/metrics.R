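#' Weighted clustering coefficients
#'
#' Two weighted generalizations of the clustering coefficient, both computed
#' after normalizing all weights by the largest edge weight in the network so
#' that both coefficients lie in \[0, 1\] and are invariant under global
#' rescaling of the weights.
#'
#' `onnela_clustering()` uses the geometric mean of triangle weights and the
#' node's (binary) degree: with normalized weights `w` and `k_i` nonzero
#' neighbors, `C_i = 2 / (k_i (k_i - 1)) * sum over neighbor pairs (j, h) of
#' (w_ij w_ih w_jh)^(1/3)`; nodes with fewer than two neighbors get 0.
#'
#' `gzh_clustering()` (Grindrod-Zhang-Horvath) depends on weights only:
#' `C_i = sum_{j != h} w_ij w_jh w_hi / ((sum_j w_ij)^2 - sum_j w_ij^2)`,
#' with 0 where the denominator vanishes. On a 0/max-weight (binary) graph it
#' reduces to the ordinary binary clustering coefficient.
#'
#' @param m symmetric non-negative matrix with at least one positive weight.
#' @return numeric vector of per-node coefficients.
#' @export
onnela_clustering <- function(m) {
  w <- .normalized_weights(m)
  a <- (w > 0) * 1
  k <- rowSums(a)
  num <- diag((w^(1 / 3)) %*% (w^(1 / 3)) %*% (w^(1 / 3)))
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, num / denom, 0)
  unname(out)
}

#' @rdname onnela_clustering
#' @export
gzh_clustering <- function(m) {
  w <- .normalized_weights(m)
  num <- diag(w %*% w %*% w)
  s1 <- rowSums(w)
  s2 <- rowSums(w^2)
  denom <- s1^2 - s2
  unname(ifelse(denom > 0, num / denom, 0))
}

.normalized_weights <- function(m) {
  m <- .validate_conn_matrix(m)
  mx <- max(m)
  if (mx <= 0) stop("degenerate input: all-zero matrix")
  m / mx
}

#' Transform connectivity weights to distances
#'
#' Strong connections should be short: `d = 1 / w` for positive weights;
#' absent edges have no direct distance (`Inf`); the diagonal is 0. Doubling
#' all weights halves every shortest-path length.
#'
#' @param m symmetric non-negative matrix.
#' @return distance matrix with `Inf` for absent edges.
#' @export
weight_to_distance <- function(m) {
  m <- .validate_conn_matrix(m)
  d <- ifelse(m > 0, 1 / m, Inf)
  diag(d) <- 0
  d
}

#' All-pairs shortest path lengths
#'
#' Exact geodesics on the weighted graph defined by a direct-distance matrix,
#' via Johnson's algorithm (igraph). Unreachable pairs are `Inf`.
#'
#' @param d direct-distance matrix (non-negative, `Inf` = no edge, 0 diagonal).
#' @return matrix of geodesic distances.
#' @export
shortest_paths_matrix <- function(d) {
  stopifnot(nrow(d) == ncol(d), all(d[is.finite(d)] >= 0))
  n <- nrow(d)
  adj <- d
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  out <- igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "johnson")
  dimnames(out) <- NULL
  out
}

#' Mean shortest path length over connected pairs
#'
#' Averages the geodesic lengths of unordered distinct node pairs with a finite
#' path; unreachable pairs are excluded and counted separately (a pruned
#' network can disconnect, and the small-world index needs a finite mean).
#'
#' @param geo geodesic matrix from [shortest_paths_matrix()].
#' @return list with `L` (mean finite geodesic) and `n_infinite_pairs`.
#' @export
average_path_length <- function(geo) {
  v <- geo[upper.tri(geo)]
  fin <- is.finite(v)
  if (!any(fin)) stop("no finite node pairs: graph fully disconnected")
  list(L = mean(v[fin]), n_infinite_pairs = sum(!fin))
}

#' Weighted betweenness centrality
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node (fractional credit for ties), on the `1/w` distance graph, normalized
#' by `(N-1)(N-2)/2`.
#'
#' @param m symmetric non-negative connectivity matrix.
#' @return numeric vector of per-node centralities in \[0, 1\].
#' @export
betweenness_centrality <- function(m) {
  m <- .validate_conn_matrix(m)
  n <- nrow(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, weights = 1 / igraph::E(g)$weight)
  unname(b) / ((n - 1) * (n - 2) / 2)
}

#' Weight-shuffled null network
#'
#' Uniformly permutes the multiset of all upper-triangle entries (zeros
#' included) over the upper-triangle positions, mirrors for symmetry, and
#' zeroes the diagonal. The null network therefore has exactly the same
#' overall connectivity histogram as the input.
#'
#' @param m symmetric non-negative matrix.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return shuffled matrix.
#' @export
shuffle_null <- function(m, seed = NULL) {
  m <- .validate_conn_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(m)
  out <- matrix(0, nrow(m), ncol(m))
  out[ut] <- sample(m[ut])
  out + t(out)
}

#' Small-world index against weight-shuffled nulls
#'
#' Computes the mean clustering coefficient `C` and mean shortest path length
#' `L` of the input, the same quantities averaged over `n_rand` weight-shuffled
#' null networks, and reports the normalized clustering coefficient
#' `gamma = C / C_rand`, normalized path length `lambda = L / L_rand`, and the
#' small-world index `sigma = gamma / lambda`. A network is said to be
#' small-world when `sigma` is well above 1: much more clustered than its
#' random counterpart at comparable path length.
#'
#' @param m symmetric non-negative connectivity matrix.
#' @param n_rand number of null networks (default 1000).
#' @param seed integer seed for the null ensemble.
#' @param cc_formula `"onnela"` or `"gzh"` clustering coefficient.
#' @return an object of class `small_world_report`: list with `cc_mean`,
#'   `path_mean`, `cc_rand_mean`, `path_rand_mean`, `gamma`, `lambda`,
#'   `sw_index`, `n_rand`, `cc_formula`, `n_infinite_pairs`.
#' @export
small_world_index <- function(m, n_rand = 1000L, seed = 1L,
                              cc_formula = c("onnela", "gzh")) {
  cc_formula <- match.arg(cc_formula)
  stopifnot(n_rand >= 1L)
  m <- .validate_conn_matrix(m)
  ccf <- if (cc_formula == "onnela") onnela_clustering else gzh_clustering
  cc <- mean(ccf(m))
  apl <- average_path_length(shortest_paths_matrix(weight_to_distance(m)))
  set.seed(seed)
  cc_r <- numeric(n_rand); l_r <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    null <- shuffle_null(m, seed = NULL)
    cc_r[r] <- mean(ccf(null))
    geo <- shortest_paths_matrix(weight_to_distance(null))
    v <- geo[upper.tri(geo)]
    fin <- is.finite(v)
    if (!any(fin)) stop("null networks fully disconnected")
    l_r[r] <- mean(v[fin])
  }
  gamma <- cc / mean(cc_r)
  lambda <- apl$L / mean(l_r)
  structure(list(cc_mean = cc, path_mean = apl$L,
                 cc_rand_mean = mean(cc_r), path_rand_mean = mean(l_r),
                 gamma = gamma, lambda = lambda, sw_index = gamma / lambda,
                 n_rand = as.integer(n_rand), cc_formula = cc_formula,
                 n_infinite_pairs = apl$n_infinite_pairs),
            class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  cat(sprintf(paste0("small_world_report (%s): C = %.4f, L = %.4f, ",
                     "gamma = %.3f, lambda = %.3f, sigma = %.3f (n_rand = %d)\n"),
              x$cc_formula, x$cc_mean, x$path_mean, x$gamma, x$lambda,
              x$sw_index, x$n_rand))
  invisible(x)
}
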