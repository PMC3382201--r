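#' Cluster hierarchy trees
#'
#' A `cluster_tree` represents a rooted hierarchy of node-index clusters as a
#' list of tiers. Tier 0 is the root (all nodes); every subsequent tier is a
#' full partition of the node set, obtained by splitting some clusters of the
#' previous tier and carrying the others down unchanged. Each cluster records
#' its member indices, the index of its parent in the previous tier, whether it
#' was carried down unsplit, and (for trees produced by [cluster_recursive()])
#' the quality curve of the split decision.
#'
#' @param tiers list of tiers; each tier is a list of clusters, a cluster being
#'   `list(members, parent, carried, quality)`.
#' @param n_nodes total number of nodes.
#' @return an object of class `cluster_tree`.
#' @keywords internal
new_cluster_tree <- function(tiers, n_nodes) {
  structure(list(tiers = tiers, n_nodes = n_nodes), class = "cluster_tree")
}

new_cluster <- function(members, parent = NA_integer_, carried = FALSE,
                        quality = NULL) {
  list(members = as.integer(members), parent = as.integer(parent),
       carried = carried, quality = quality)
}

#' Validate a cluster tree
#'
#' Checks that every tier partitions `1..n_nodes`, that parents contain their
#' children, and that tier 0 is the single root cluster.
#'
#' @param tree a `cluster_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_cluster_tree <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- tree$n_nodes
  if (length(tree$tiers) < 1L || length(tree$tiers[[1L]]) != 1L)
    stop("tree must have a single root cluster at tier 0")
  if (!setequal(tree$tiers[[1L]][[1L]]$members, seq_len(n)))
    stop("root cluster must contain all nodes")
  for (t in seq_along(tree$tiers)) {
    tier <- tree$tiers[[t]]
    all_members <- unlist(lapply(tier, `[[`, "members"))
    if (length(all_members) != n || anyDuplicated(all_members) ||
        !setequal(all_members, seq_len(n)))
      stop(sprintf("tier %d does not partition the node set", t - 1L))
    if (t > 1L) {
      for (cl in tier) {
        par <- tree$tiers[[t - 1L]][[cl$parent]]
        if (!all(cl$members %in% par$members))
          stop(sprintf("cluster at tier %d not contained in its parent", t - 1L))
      }
    }
  }
  invisible(tree)
}

#' Number of tiers below the root
#' @param tree a `cluster_tree`.
#' @return integer depth (0 for a root-only tree).
#' @export
tree_n_tiers <- function(tree) length(tree$tiers) - 1L

#' Clusters at a given tier
#'
#' @param tree a `cluster_tree`.
#' @param tier tier index, 0 = root.
#' @return list of integer vectors (cluster member indices).
#' @export
clusters_at_tier <- function(tree, tier) {
  if (tier < 0L || tier > tree_n_tiers(tree))
    stop(sprintf("tier %d not present in tree (0..%d)", tier, tree_n_tiers(tree)))
  lapply(tree$tiers[[tier + 1L]], `[[`, "members")
}

#' Tree distance between two clusters of the same tier
#'
#' The tree distance is the number of tiers one must ascend from the clusters'
#' own tier before they first share an ancestor: 0 for the same cluster, 1 for
#' siblings, and so on.
#'
#' @param tree a `cluster_tree`.
#' @param tier tier at which both clusters live.
#' @param i,j cluster indices within that tier.
#' @return non-negative integer.
#' @export
tree_distance <- function(tree, tier, i, j) {
  k <- tier + 1L
  if (k < 1L || k > length(tree$tiers)) stop("tier not present in tree")
  nt <- length(tree$tiers[[k]])
  if (i < 1L || i > nt || j < 1L || j > nt)
    stop("cluster index out of range for this tier")
  d <- 0L
  while (i != j) {
    i <- tree$tiers[[k]][[i]]$parent
    j <- tree$tiers[[k]][[j]]$parent
    k <- k - 1L
    d <- d + 1L
    if (k < 1L) stop("clusters share no ancestor; malformed tree")
  }
  d
}

#' Balanced recursive bisection tree
#'
#' Splits `1..n_nodes` recursively into halves down to `depth` tiers, the
#' remainder of an odd split going to the left child. This is the planted
#' topology used by the synthetic cohort generator.
#'
#' @param n_nodes number of nodes; must be at least `2^depth`.
#' @param depth number of bipartition tiers.
#' @return a `cluster_tree` of depth `depth`.
#' @export
balanced_bisection_tree <- function(n_nodes, depth) {
  n_nodes <- as.integer(n_nodes); depth <- as.integer(depth)
  if (n_nodes < 2L^depth)
    stop("invalid config: n_nodes must be at least 2^depth so every leaf is non-empty")
  tiers <- list(list(new_cluster(seq_len(n_nodes))))
  for (t in seq_len(depth)) {
    prev <- tiers[[t]]
    cur <- list()
    for (pi in seq_along(prev)) {
      m <- prev[[pi]]$members
      nl <- ceiling(length(m) / 2)
      cur <- c(cur,
               list(new_cluster(m[seq_len(nl)], parent = pi),
                    new_cluster(m[(nl + 1L):length(m)], parent = pi)))
    }
    tiers[[t + 1L]] <- cur
  }
  new_cluster_tree(tiers, n_nodes)
}

# Logical children of cluster `idx` at tier `tier` (next-tier clusters whose
# parent is idx). A single carried-down child means the node was not split.
.tree_children <- function(tree, tier, idx) {
  if (tier + 2L > length(tree$tiers)) return(integer(0))
  nxt <- tree$tiers[[tier + 2L]]
  which(vapply(nxt, function(cl) cl$parent == idx, logical(1)))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d nodes, %d tier(s)\n", x$n_nodes, tree_n_tiers(x)))
  for (t in seq_along(x$tiers)) {
    sizes <- vapply(x$tiers[[t]], function(cl) length(cl$members), integer(1))
    cat(sprintf("  tier %d: %d cluster(s), sizes %s\n", t - 1L, length(sizes),
                paste(sizes, collapse = "/")))
  }
  invisible(x)
}
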