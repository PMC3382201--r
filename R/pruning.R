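#' Pooled variance of nonzero connectivity entries
#'
#' Population-form variance (denominator n) of the multiset of all strictly
#' positive upper-triangle entries pooled across every subject, computed about
#' the pooled mean. This is the noise-scale estimate used by the pruning
#' z-test.
#'
#' @param stack a [subject_stack()].
#' @return numeric scalar.
#' @export
joint_nonzero_variance <- function(stack) {
  vals <- .pooled_nonzero(stack$matrices)
  if (!length(vals)) stop("degenerate input: no nonzero upper-triangle entries")
  mean((vals - mean(vals))^2)
}

.pooled_nonzero <- function(mats) {
  ut <- upper.tri(mats[[1L]])
  unlist(lapply(mats, function(m) { v <- m[ut]; v[v > 0] }), use.names = FALSE)
}

#' One-sided z-test of a single edge against the zero-mean null
#'
#' Tests whether the S per-subject weights of one edge (zeros included for
#' subjects lacking it) are consistent with zero-mean noise of variance
#' `sigma2`. The statistic is `z = mean(values) * sqrt(S) / sigma`; the edge is
#' kept iff the upper-tail null is refuted at level `p`, i.e.
#' `z > qnorm(1 - p)`. The test is one-sided because connectivity weights are
#' non-negative, so only departures above zero are meaningful.
#'
#' @param values numeric vector of length S >= 2.
#' @param sigma2 pooled variance, must be positive.
#' @param p significance level in (0, 1].
#' @return list with `keep` (logical) and `z` (the statistic).
#' @export
edge_z_test <- function(values, sigma2, p) {
  stopifnot(length(values) >= 2L, sigma2 > 0, p > 0, p <= 1)
  z <- mean(values) * sqrt(length(values)) / sqrt(sigma2)
  list(keep = z > stats::qnorm(1 - p), z = z)
}

#' Iterative statistical pruning of questionable edges
#'
#' Alternates two steps until the surviving-edge set stabilizes: (1) recompute
#' the pooled variance of all surviving nonzero entries
#' ([joint_nonzero_variance()]); (2) re-test every surviving edge with the
#' one-sided z-test ([edge_z_test()]) and zero out, in every subject, the edges
#' that fail. Dropped edges never return, so the survivor set is monotonically
#' non-increasing and termination is guaranteed. If at any iteration all
#' surviving entries are identical (pooled variance 0), the zero-mean noise
#' null is untenable for any positive weight, so all surviving edges are kept
#' and the loop stops; this degenerate branch is noted in the result.
#'
#' At `p = 1` the critical value is `-Inf`, every edge passes, and the stack is
#' returned unchanged after a single iteration.
#'
#' @param stack a [subject_stack()].
#' @param p significance level in (0, 1].
#' @param max_iter iteration safety cap (default 100).
#' @return an object of class `prune_result`: list with `keep_mask`
#'   (symmetric logical, FALSE on the diagonal and wherever the pruned average
#'   matrix is zero), `pruned_stack`, `average_matrix`, `per_edge_z`
#'   (z statistics from the iteration at which each edge was last tested),
#'   `joint_variance_trace`, `n_iterations`, `significance`, and `notes`.
#' @export
prune_iterative <- function(stack, p, max_iter = 100L) {
  stack <- validate_subject_stack(stack)
  stopifnot(p > 0, p <= 1)
  mats <- stack$matrices
  s <- length(mats)
  n <- nrow(mats[[1L]])
  ut_idx <- which(upper.tri(mats[[1L]]))
  vals <- vapply(mats, function(m) m[ut_idx], numeric(length(ut_idx))) # |ut| x S
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(ut_idx))

  alive <- rowSums(vals > 0) > 0L           # candidate edges: nonzero somewhere
  if (!any(alive)) stop("degenerate input: all-zero stack")
  zcrit <- stats::qnorm(1 - p)
  zmat <- rep(NA_real_, length(ut_idx))
  trace <- numeric(0)
  notes <- character(0)
  iter <- 0L

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("pruning failed to converge within max_iter iterations")
    pooled <- vals[alive, , drop = FALSE]
    pooled <- pooled[pooled > 0]
    if (!length(pooled)) { alive[] <- FALSE; notes <- c(notes, "all edges pruned"); break }
    sigma2 <- mean((pooled - mean(pooled))^2)
    trace <- c(trace, sigma2)
    if (sigma2 == 0) {
      notes <- c(notes, "pooled variance reached 0; kept all surviving nonzero edges")
      zmat[alive] <- Inf
      break
    }
    z <- rowMeans(vals[alive, , drop = FALSE]) * sqrt(s) / sqrt(sigma2)
    zmat[alive] <- z
    keep <- z > zcrit
    if (all(keep)) break
    dropped <- which(alive)[!keep]
    vals[dropped, ] <- 0
    alive[dropped] <- FALSE
    if (!any(alive)) { notes <- c(notes, "all edges pruned"); break }
  }

  pruned <- lapply(seq_len(s), function(k) {
    m <- matrix(0, n, n)
    m[ut_idx] <- vals[, k]
    m + t(m)
  })
  keep_mask <- matrix(FALSE, n, n)
  keep_mask[ut_idx] <- alive
  keep_mask <- keep_mask | t(keep_mask)
  per_edge_z <- matrix(0, n, n)
  per_edge_z[ut_idx] <- ifelse(is.na(zmat), 0, zmat)
  per_edge_z <- per_edge_z + t(per_edge_z)
  avg <- Reduce(`+`, pruned) / s
  keep_mask[avg == 0] <- FALSE

  structure(list(keep_mask = keep_mask,
                 pruned_stack = subject_stack(pruned,
                                              roi_labels = stack$roi_labels,
                                              subject_ids = stack$subject_ids),
                 average_matrix = avg,
                 per_edge_z = per_edge_z,
                 joint_variance_trace = trace,
                 n_iterations = iter,
                 significance = p,
                 notes = c(notes,
                           "per-edge samples include zeros from subjects lacking the edge",
                           "one-sided upper-tail z-test")),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  n_kept <- sum(x$keep_mask[upper.tri(x$keep_mask)])
  cat(sprintf("prune_result: p = %g, %d iterations, %d surviving upper-triangle edges\n",
              x$significance, x$n_iterations, n_kept))
  invisible(x)
}
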