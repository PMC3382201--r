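#' Synthetic cohort generator configuration
#'
#' Parameters of the planted-hierarchy connectome generator. Defaults mirror
#' the dimensions and empirical structure of a 14-subject, 90-region
#' diffusion-MRI cohort: approximately exponential edge weights, a base-2
#' hierarchical community structure of 3 tiers, a 3.8-fold drop in mean
#' connectivity per tree-distance level, a small rate of low-weight spurious
#' edges appearing independently per subject, and moderate multiplicative
#' between-subject variability. The default edge density (0.55) is set in the
#' regime where the planted hierarchy is statistically identifiable by the
#' spectral pipeline; at the sparsity of a typical tractography cohort
#' (a few hundred of the 4005 possible edges, `edge_density` near 0.08) many
#' nodes carry no within-cluster edge at all and no method can recover the
#' tree, so sparse settings are left to explicit opt-in.
#'
#' @param n_nodes number of regions N (default 90).
#' @param n_subjects number of subjects S (default 14).
#' @param tree_depth number of bipartition tiers of the planted hierarchy
#'   (default 3); requires `n_nodes >= 2^tree_depth`.
#' @param base_weight mean weight of an edge whose endpoints share a leaf
#'   cluster (arbitrary connectivity units; default 10).
#' @param decay_ratio multiplicative drop in mean weight per tree-distance
#'   level; must exceed 1 (default 3.8).
#' @param edge_density probability in (0, 1] that a node pair carries a true
#'   (cohort-level) edge (default 0.55).
#' @param subject_cv coefficient of variation of the per-subject multiplicative
#'   noise on each true edge weight (default 0.3; 0 disables noise).
#' @param spurious_rate probability in \[0, 1) that a pair without a true edge
#'   receives a spurious low-weight edge, drawn independently per subject
#'   (default 0.025).
#' @param spurious_scale mean weight of spurious edges (default 0.5).
#' @param seed integer RNG seed; required by [generate_cohort()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_nodes = 90L, n_subjects = 14L, tree_depth = 3L,
                             base_weight = 10, decay_ratio = 3.8,
                             edge_density = 0.55, subject_cv = 0.3,
                             spurious_rate = 0.025, spurious_scale = 0.5,
                             seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_subjects = as.integer(n_subjects),
              tree_depth = as.integer(tree_depth), base_weight = base_weight,
              decay_ratio = decay_ratio, edge_density = edge_density,
              subject_cv = subject_cv, spurious_rate = spurious_rate,
              spurious_scale = spurious_scale, seed = as.integer(seed))
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param cfg a list of generator parameters.
#' @export
validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_nodes < 2L || n_subjects < 1L || tree_depth < 1L)
      stop("invalid config: n_nodes, n_subjects, tree_depth must be positive")
    if (n_nodes < 2L^tree_depth)
      stop("invalid config: n_nodes must be at least 2^tree_depth")
    if (base_weight <= 0) stop("invalid config: base_weight must be positive")
    if (decay_ratio <= 1) stop("invalid config: decay_ratio must exceed 1")
    if (edge_density <= 0 || edge_density > 1)
      stop("invalid config: edge_density must be in (0, 1]")
    if (subject_cv < 0) stop("invalid config: subject_cv must be non-negative")
    if (spurious_rate < 0 || spurious_rate >= 1)
      stop("invalid config: spurious_rate must be in [0, 1)")
    if (spurious_scale <= 0) stop("invalid config: spurious_scale must be positive")
  })
  structure(cfg, class = "generator_config")
}

#' Read a generator configuration from a YAML (or flat key-value) file
#'
#' Unknown keys raise an error; missing keys take the package defaults.
#'
#' @param path file with `key: value` lines.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(generator_config, vals)
}

#' Planted hierarchical mean-connectivity matrix
#'
#' Splits the node set recursively into balanced halves down to
#' `cfg$tree_depth` tiers and assigns every node pair the expected edge weight
#' `base_weight / decay_ratio^t`, where `t` is the tree distance of the pair:
#' the number of tiers separating their deepest common cluster from the leaf
#' tier (0 for a pair sharing a leaf cluster).
#'
#' @param cfg a [generator_config()].
#' @return list with `expected_mean_matrix` (symmetric N x N, zero diagonal)
#'   and `tree` (the planted `cluster_tree`).
#' @export
plant_hierarchy_means <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  n <- cfg$n_nodes
  tree <- balanced_bisection_tree(n, cfg$tree_depth)
  # tree distance between nodes = depth - tier of deepest common cluster;
  # computed from leaf membership: node i is in leaf cluster leaf[i].
  leaves <- clusters_at_tier(tree, cfg$tree_depth)
  leaf_of <- integer(n)
  for (k in seq_along(leaves)) leaf_of[leaves[[k]]] <- k
  dist_leaf <- outer(seq_along(leaves), seq_along(leaves),
                     Vectorize(function(a, b) tree_distance(tree, cfg$tree_depth, a, b)))
  node_t <- dist_leaf[leaf_of, leaf_of]
  mu <- cfg$base_weight / cfg$decay_ratio^node_t
  diag(mu) <- 0
  list(expected_mean_matrix = mu, tree = tree)
}

#' Generate a synthetic multi-subject cohort with planted hierarchy
#'
#' For each node pair, a true edge is realized with probability
#' `edge_density`; its cohort-level weight is drawn from an exponential
#' distribution whose mean is the planted hierarchical mean (see
#' [plant_hierarchy_means()]). Each subject observes that weight multiplied by
#' a gamma-distributed factor with mean 1 and coefficient of variation
#' `subject_cv`. Spurious edges are then added independently per subject:
#' each pair without a true edge receives, with probability `spurious_rate`,
#' an exponential weight of mean `spurious_scale`. Because spurious edges are
#' regenerated per subject, their cross-subject means are small relative to
#' their spread, which is what makes them removable by [prune_iterative()].
#'
#' Identical seeds produce bitwise-identical cohorts.
#'
#' @param cfg a [generator_config()].
#' @return list with `stack` (a [subject_stack()]) and `truth`
#'   (list: `tree`, `support_mask`, `expected_mean_matrix`).
#' @export
generate_cohort <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  planted <- plant_hierarchy_means(cfg)
  n <- cfg$n_nodes; s <- cfg$n_subjects
  ut <- upper.tri(matrix(0, n, n))
  set.seed(cfg$seed)

  support <- matrix(FALSE, n, n)
  support[ut] <- stats::runif(sum(ut)) < cfg$edge_density
  support <- support | t(support)

  cohort_w <- matrix(0, n, n)
  idx <- which(ut & support)
  cohort_w[idx] <- stats::rexp(length(idx), rate = 1 / planted$expected_mean_matrix[idx])
  cohort_w <- cohort_w + t(cohort_w)

  mats <- vector("list", s)
  spurious_candidates <- which(ut & !support)
  for (k in seq_len(s)) {
    m <- cohort_w
    if (cfg$subject_cv > 0 && length(idx)) {
      shape <- 1 / cfg$subject_cv^2
      noise <- stats::rgamma(length(idx), shape = shape, rate = shape)
      m[idx] <- m[idx] * noise
      m[lower.tri(m)] <- 0
      m <- m + t(m)
    }
    if (cfg$spurious_rate > 0 && length(spurious_candidates)) {
      hit <- spurious_candidates[stats::runif(length(spurious_candidates)) < cfg$spurious_rate]
      m[hit] <- stats::rexp(length(hit), rate = 1 / cfg$spurious_scale)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    diag(m) <- 0
    mats[[k]] <- m
  }
  stack <- subject_stack(mats)
  list(stack = stack,
       truth = list(tree = planted$tree, support_mask = support,
                    expected_mean_matrix = planted$expected_mean_matrix))
}
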