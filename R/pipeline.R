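#' Pipeline configuration
#'
#' Bundles the inputs of the end-to-end workflow: a cohort source (a directory
#' written by [write_cohort()] or a [generator_config()] to synthesize one),
#' the sweep of pruning significance levels, the null-ensemble size for the
#' small-world stage, per-stage toggles, and the output directory.
#'
#' The clustering and tree-profile stages run once, on the cohort average
#' matrix pruned at `cluster_p`, while `p` is swept only for the edge-count,
#' degree-distribution and small-world summaries. `cluster_p` defaults to 1
#' (no pruning): subject averaging already suppresses inconsistent edges, and
#' aggressive pruning removes the weak inter-cluster edges that the decay
#' profile needs. Set it to a conservative level explicitly to cluster a
#' pruned network instead.
#'
#' @param cohort_dir directory containing a cohort, or `NULL` to generate one.
#' @param generator a [generator_config()] used when `cohort_dir` is `NULL`.
#' @param p_levels pruning significance sweep (default `1e-9, 1e-5, 1e-3, 1`).
#' @param n_rand null networks per small-world estimate (default 100).
#' @param seed seed for the stochastic stages (null ensembles).
#' @param out_dir output directory.
#' @param cluster_p pruning level feeding the clustering stage (default 1,
#'   i.e. unpruned).
#' @param max_tiers,c_max recursion depth and largest group number for the
#'   clustering stage.
#' @param profile_tier tier at which the inter-cluster decay profile is taken
#'   (default 2).
#' @param stages character subset of
#'   `c("prune", "degree", "metrics", "cluster", "profile")`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, generator = generator_config(),
                            p_levels = c(1e-9, 1e-5, 1e-3, 1),
                            n_rand = 100L, seed = 1L, out_dir = "results",
                            cluster_p = 1, max_tiers = 3L, c_max = 8L,
                            profile_tier = 2L,
                            stages = c("prune", "degree", "metrics",
                                       "cluster", "profile")) {
  stopifnot(all(p_levels > 0), all(p_levels <= 1), length(stages) >= 1L)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort_dir = cohort_dir, generator = generator,
                 p_levels = p_levels, n_rand = as.integer(n_rand),
                 seed = as.integer(seed), out_dir = out_dir,
                 cluster_p = cluster_p, max_tiers = as.integer(max_tiers),
                 c_max = as.integer(c_max),
                 profile_tier = as.integer(profile_tier), stages = stages),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Polynomial rolling hash of the serialized configuration, for the run
# manifest (stable across sessions; not cryptographic).
.config_hash <- function(cfg) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(cfg)), collapse = "\n"))
  h <- 17
  for (b in s) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full weighted-connectome analysis pipeline
#'
#' Loads or generates a cohort, then for every pruning level computes the
#' surviving edge count, the degree-distribution model comparison (KS distance
#' per family), and the small-world report under both clustering-coefficient
#' formulas; finally clusters the average matrix pruned at `cluster_p` into a
#' hierarchy tree and profiles inter-cluster connectivity against tree
#' distance. Writes, under `out_dir`: `ks_table.tsv` (family x pruning level),
#' `small_world.tsv`, `edge_counts.tsv`, `quality_curves.tsv`, `tree.nwk`,
#' `tree_profile.tsv`, and a machine-readable `manifest.json` (package version,
#' seeds, configuration and its hash) that guarantees exact reproducibility.
#' A failing stage aborts with the stage named; outputs already written are
#' retained.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- .stage("cohort", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else generate_cohort(config$generator)$stack
  })

  results <- list(config = config)
  prunes <- list()
  if (any(c("prune", "degree", "metrics", "cluster", "profile") %in% config$stages)) {
    prunes <- .stage("prune", {
      out <- lapply(config$p_levels, function(p) prune_iterative(cohort, p))
      names(out) <- formatC(config$p_levels, format = "g")
      out
    })
    results$prune <- prunes
    .write_tsv(data.frame(
      p = names(prunes),
      n_edges = vapply(prunes, function(pr) sum(pr$keep_mask[upper.tri(pr$keep_mask)]), integer(1)),
      n_iterations = vapply(prunes, function(pr) pr$n_iterations, integer(1))),
      file.path(config$out_dir, "edge_counts.tsv"))
  }

  if ("degree" %in% config$stages) {
    results$degree <- .stage("degree", {
      lapply(prunes, function(pr) compare_fits(weighted_degrees(pr$pruned_stack)$degree))
    })
    ks_tab <- do.call(rbind, lapply(names(results$degree), function(p) {
      tab <- results$degree[[p]]
      data.frame(p = p, family = tab$family, ks_distance = tab$ks_distance,
                 support = tab$support, n_used = tab$n_used)
    }))
    .write_tsv(ks_tab, file.path(config$out_dir, "ks_table.tsv"))
  }

  if ("metrics" %in% config$stages) {
    results$small_world <- .stage("metrics", {
      out <- list()
      for (p in names(prunes)) {
        avg <- prunes[[p]]$average_matrix
        for (ccf in c("onnela", "gzh")) {
          out[[paste(p, ccf, sep = "/")]] <-
            small_world_index(avg, n_rand = config$n_rand,
                              seed = config$seed, cc_formula = ccf)
        }
      }
      out
    })
    sw_tab <- do.call(rbind, lapply(names(results$small_world), function(k) {
      r <- results$small_world[[k]]
      data.frame(p = sub("/.*", "", k), cc_formula = r$cc_formula,
                 C = r$cc_mean, L = r$path_mean, gamma = r$gamma,
                 lambda = r$lambda, sigma = r$sw_index,
                 n_infinite_pairs = r$n_infinite_pairs)
    }))
    .write_tsv(sw_tab, file.path(config$out_dir, "small_world.tsv"))
  }

  if (any(c("cluster", "profile") %in% config$stages)) {
    cl_key <- formatC(config$cluster_p, format = "g")
    avg <- if (cl_key %in% names(prunes)) prunes[[cl_key]]$average_matrix
           else prune_iterative(cohort, config$cluster_p)$average_matrix
    results$tree <- .stage("cluster", {
      cluster_recursive(avg, max_tiers = config$max_tiers, c_max = config$c_max)
    })
    write_tree_newick(results$tree, cohort$roi_labels,
                      file.path(config$out_dir, "tree.nwk"))
    qrows <- list()
    for (t in seq_along(results$tree$tiers)) {
      for (ci in seq_along(results$tree$tiers[[t]])) {
        qc <- results$tree$tiers[[t]][[ci]]$quality
        if (is.null(qc)) next
        qrows[[length(qrows) + 1L]] <- data.frame(
          tier = t - 1L, cluster = ci, C = qc$group_numbers,
          cost = qc$costs, quality = qc$qualities, selected = qc$selected)
      }
    }
    if (length(qrows))
      .write_tsv(do.call(rbind, qrows), file.path(config$out_dir, "quality_curves.tsv"))

    if ("profile" %in% config$stages) {
      tier <- min(config$profile_tier, tree_n_tiers(results$tree))
      results$profile <- .stage("profile", distance_profile(avg, results$tree, tier))
      prof <- results$profile$profile
      prof$log_mean_connectivity <- ifelse(prof$mean_connectivity > 0,
                                           log(prof$mean_connectivity), NA)
      .write_tsv(prof, file.path(config$out_dir, "tree_profile.tsv"))
    }
  }

  manifest <- list(
    package = "hierconn",
    version = as.character(utils::packageVersion("hierconn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    generator_seed = if (is.null(config$cohort_dir)) config$generator$seed else NA,
    config = unclass(config)[setdiff(names(config), "generator")],
    generator = if (is.null(config$cohort_dir)) unclass(config$generator) else NULL,
    config_hash = .config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
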