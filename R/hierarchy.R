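#' Symmetrically normalized graph operator
#'
#' `L = D^{-1/2} W D^{-1/2}` with `D_ii = sum_j w_ij`, the symmetric
#' normalization used by the multi-eigenvector normalized-cuts family of
#' spectral methods. The operator is symmetric with eigenvalues in \[-1, 1\];
#' its top eigenvectors carry the cluster structure.
#'
#' @param w symmetric non-negative matrix without zero-degree nodes (assign
#'   isolates to singleton clusters before calling).
#' @return symmetric matrix.
#' @export
normalized_laplacian <- function(w) {
  w <- .validate_conn_matrix(w)
  deg <- rowSums(w)
  if (any(deg == 0)) stop("isolated node: zero-degree rows are not admissible")
  s <- 1 / sqrt(deg)
  w * outer(s, s)
}

#' Leading eigenvectors of a symmetric operator
#'
#' Columns are orthonormal eigenvectors of the C algebraically largest
#' eigenvalues, with a deterministic sign convention: the largest-magnitude
#' entry of each column (first on ties) is made positive.
#'
#' @param l symmetric matrix.
#' @param c_groups number of eigenvectors, at most `nrow(l)`.
#' @return N x C matrix with orthonormal columns; eigenvalues as attribute
#'   `values`.
#' @export
top_eigenvectors <- function(l, c_groups) {
  stopifnot(c_groups >= 1L, c_groups <= nrow(l))
  e <- eigen(l, symmetric = TRUE)
  x <- e$vectors[, seq_len(c_groups), drop = FALSE]
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(x[, j]))
    if (x[i, j] < 0) x[, j] <- -x[, j]
  }
  attr(x, "values") <- e$values[seq_len(c_groups)]
  x
}

# Product of Givens rotations over all coordinate pairs, in fixed pair order.
.givens_product <- function(theta, pairs, c_groups) {
  r <- diag(c_groups)
  for (k in seq_along(theta)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cs <- cos(theta[k]); sn <- sin(theta[k])
    ri <- r[, i]; rj <- r[, j]
    r[, i] <- cs * ri - sn * rj
    r[, j] <- sn * ri + cs * rj
  }
  r
}

.alignment_cost <- function(z) {
  z2 <- z * z
  mi2 <- z2[cbind(seq_len(nrow(z2)), max.col(z2, ties.method = "first"))]
  # an all-zero row is alignment-invariant; it contributes its minimum, 1
  ok <- mi2 > 0
  sum(z2[ok, , drop = FALSE] / mi2[ok]) + sum(!ok)
}

# Analytic gradient of the alignment cost with respect to the Givens angles
# (max treated as locally constant in position, exact away from ties).
.alignment_gradient <- function(theta, x, pairs, c_groups) {
  kk <- length(theta)
  gs <- vector("list", kk)
  for (k in seq_len(kk)) {
    g <- diag(c_groups)
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cs <- cos(theta[k]); sn <- sin(theta[k])
    g[i, i] <- cs; g[j, j] <- cs; g[i, j] <- sn; g[j, i] <- -sn
    gs[[k]] <- g
  }
  pre <- vector("list", kk + 1L); pre[[1L]] <- diag(c_groups)
  for (k in seq_len(kk)) pre[[k + 1L]] <- pre[[k]] %*% gs[[k]]
  suf <- vector("list", kk + 1L); suf[[kk + 1L]] <- diag(c_groups)
  for (k in rev(seq_len(kk))) suf[[k]] <- gs[[k]] %*% suf[[k + 1L]]

  z <- x %*% pre[[kk + 1L]]
  z2 <- z * z
  jstar <- max.col(z2, ties.method = "first")
  rows <- seq_len(nrow(z))
  mi2 <- z2[cbind(rows, jstar)]
  ok <- mi2 > 0
  fi <- rowSums(z2)
  grad <- numeric(kk)
  for (k in seq_len(kk)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    vk <- matrix(0, c_groups, c_groups)
    cs <- cos(theta[k]); sn <- sin(theta[k])
    vk[i, i] <- -sn; vk[j, j] <- -sn; vk[i, j] <- cs; vk[j, i] <- -cs
    dz <- x %*% (pre[[k]] %*% vk %*% suf[[k + 1L]])
    term1 <- 2 * rowSums(z * dz)
    term2 <- 2 * z[cbind(rows, jstar)] * dz[cbind(rows, jstar)]
    grad[k] <- sum((term1[ok] - fi[ok] * term2[ok] / mi2[ok]) / mi2[ok])
  }
  grad
}

#' Align eigenvector columns with the canonical axes via Givens rotations
#'
#' Searches the rotation `R`, parameterized by `K = C(C-1)/2` Givens angles,
#' that minimizes the alignment cost
#' `J = sum_i sum_j Z_ij^2 / max_j(Z_ij^2)` of `Z = X R`. The cost is bounded
#' between `n` (exactly one nonzero per row: a perfect cluster indicator up to
#' scaling) and `nC`, and is minimized by gradient-based descent (BFGS) over
#' the angle vector from a small fixed set of deterministic starting points;
#' the best converged solution is returned. Results are deterministic.
#'
#' @param x N x C matrix with orthonormal columns (C >= 2).
#' @param n_starts number of deterministic starting angle vectors (default 5).
#' @param max_iter BFGS iteration cap per start (default 500).
#' @return list with `R` (C x C rotation), `Z = x %*% R`, `J` (cost), and
#'   `theta` (the Givens angles).
#' @export
align_rotation <- function(x, n_starts = 5L, max_iter = 500L) {
  c_groups <- ncol(x)
  if (is.null(c_groups) || c_groups < 2L) stop("alignment needs at least 2 columns")
  gram <- crossprod(x)
  if (max(abs(gram - diag(c_groups))) > 1e-8)
    stop("domain error: columns of x must be orthonormal")
  pairs <- utils::combn(c_groups, 2L)
  kk <- ncol(pairs)
  obj <- function(theta) .alignment_cost(x %*% .givens_product(theta, pairs, c_groups))
  grd <- function(theta) .alignment_gradient(theta, x, pairs, c_groups)
  # deterministic starts: zero plus fixed low-discrepancy angle vectors
  starts <- lapply(seq_len(n_starts) - 1L, function(s) {
    if (s == 0L) rep(0, kk)
    else (((s * seq_len(kk) * 0.6180339887) %% 1) - 0.5) * pi / 2
  })
  if (kk == 1L) {
    # C = 2: one angle with period pi/2; seed the descent from a fine grid
    grid <- seq(-pi / 4, pi / 4, length.out = 91L)
    starts <- as.list(grid[order(vapply(grid, obj, numeric(1)))[1:3]])
  }
  best <- NULL
  for (th0 in starts) {
    res <- stats::optim(th0, obj, gr = grd, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-12))
    if (is.null(best) || res$value < best$value) best <- res
  }
  r <- .givens_product(best$par, pairs, c_groups)
  list(R = r, Z = x %*% r, J = best$value, theta = best$par)
}

#' Quality of an alignment cost
#'
#' Rescales the alignment cost `J` from its provable range `[n, nC]` onto
#' `[0, 1]`, 1 being perfect (one nonzero per row):
#' `q = 1 - (J - n) / (n (C - 1))`.
#'
#' @param j alignment cost.
#' @param n number of rows.
#' @param c_groups number of clusters (>= 2).
#' @return numeric in \[0, 1\].
#' @export
quality <- function(j, n, c_groups) {
  if (c_groups < 2L) stop("quality undefined for fewer than 2 groups")
  stopifnot(j >= n - 1e-8 * n, j <= n * c_groups + 1e-8 * n * c_groups)
  min(1, max(0, 1 - (j - n) / (n * (c_groups - 1))))
}

#' Alignment quality across candidate group numbers
#'
#' For each `C` in `2..c_max`, aligns the top C eigenvectors of the normalized
#' operator of `w` and records the cost `J(C)` and quality `q(C)`. The selected
#' group number `C*` is the largest C whose quality is within the relative
#' tolerance `select_tol` of the maximum quality (the "largest group number
#' with maximal quality" rule, made robust to floating point). The default
#' tolerance, 1e-6, is at the scale of optimizer noise: a looser band would
#' treat genuinely different split qualities as ties and systematically
#' over-partition nested structure.
#'
#' @param w symmetric non-negative connectivity matrix.
#' @param c_max largest candidate group number (default 8, capped at N).
#' @param select_tol relative tolerance within which qualities count as tied
#'   with the maximum for the largest-C selection rule (default 1e-6).
#' @return an object of class `quality_curve`: list with `group_numbers`,
#'   `costs`, `qualities`, `selected`, and `Z` (aligned embeddings per C).
#' @export
quality_curve <- function(w, c_max = 8L, select_tol = 1e-6) {
  w <- .validate_conn_matrix(w)
  n <- nrow(w)
  # C = N is excluded: a full orthogonal basis aligns perfectly for any input,
  # so q(N) = 1 trivially and would always win the selection rule.
  c_max <- min(as.integer(c_max), n - 1L)
  if (c_max < 2L) stop("c_max must be at least 2")
  l <- normalized_laplacian(w)
  ev <- top_eigenvectors(l, c_max)
  cs <- 2L:c_max
  costs <- numeric(length(cs)); quals <- numeric(length(cs))
  zs <- vector("list", length(cs))
  for (k in seq_along(cs)) {
    al <- align_rotation(ev[, seq_len(cs[k]), drop = FALSE])
    costs[k] <- al$J
    quals[k] <- quality(al$J, n, cs[k])
    zs[[k]] <- al$Z
  }
  qmax <- max(quals)
  sel <- cs[max(which(quals >= qmax - select_tol * abs(qmax)))]
  structure(list(group_numbers = cs, costs = costs, qualities = quals,
                 selected = sel, Z = zs),
            class = "quality_curve")
}

#' @export
print.quality_curve <- function(x, ...) {
  cat("quality_curve: C* =", x$selected, "\n")
  print(data.frame(C = x$group_numbers, J = round(x$costs, 4),
                   q = round(x$qualities, 4)))
  invisible(x)
}

#' Cluster labels from an aligned embedding
#'
#' Assigns each row to the cluster of its squared-maximal aligned entry;
#' exact ties go to the lowest cluster index.
#'
#' @param z aligned N x C matrix (from [align_rotation()]).
#' @return integer labels in `1..C`.
#' @export
assign_clusters <- function(z) {
  max.col(z * z, ties.method = "first")
}

#' SVD-based discretization of a spectral embedding
#'
#' Alternates (a) binarizing each row of the rotated embedding to its maximal
#' entry and (b) finding, by singular value decomposition, the orthogonal
#' rotation best aligning the embedding with the binarized matrix, until the
#' label assignment is stable. Rows are first normalized to unit length; the
#' initial rotation is built deterministically from greedily selected,
#' maximally orthogonal rows. This is an independent discretization route used
#' to cross-check [assign_clusters()].
#'
#' @param x N x C matrix with orthonormal columns.
#' @param max_iter iteration cap (default 100).
#' @return integer labels in `1..C`; attribute `converged` is FALSE (with a
#'   warning) if the alternation still oscillated at `max_iter`.
#' @export
discretize_svd <- function(x, max_iter = 100L) {
  c_groups <- ncol(x)
  rn <- sqrt(rowSums(x^2))
  rn[rn == 0] <- 1
  xt <- x / rn
  # deterministic init: greedily pick maximally mutually-orthogonal rows
  r <- matrix(0, c_groups, c_groups)
  r[, 1L] <- xt[1L, ]
  acc <- rep(0, nrow(xt))
  for (j in 2L:c_groups) {
    acc <- acc + abs(xt %*% r[, j - 1L, drop = FALSE])[, 1L]
    cand <- xt[which.min(acc), ]
    for (jj in seq_len(j - 1L)) cand <- cand - sum(cand * r[, jj]) * r[, jj]
    nc <- sqrt(sum(cand^2))
    r[, j] <- if (nc > 1e-12) cand / nc else .orthocomplement_col(r[, seq_len(j - 1L), drop = FALSE])
  }
  labels <- rep(0L, nrow(xt))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mzt <- xt %*% r
    new_labels <- max.col(mzt, ties.method = "first")
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    y <- matrix(0, nrow(xt), c_groups)
    y[cbind(seq_len(nrow(xt)), labels)] <- 1
    sv <- svd(crossprod(xt, y))
    r <- sv$u %*% t(sv$v)
  }
  if (!converged) warning("SVD discretization did not stabilize; returning last labels")
  structure(labels, converged = converged)
}

.orthocomplement_col <- function(basis) {
  c_groups <- nrow(basis)
  for (trial in seq_len(c_groups)) {
    v <- rep(0, c_groups); v[trial] <- 1
    v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(as.numeric(v) / nv)
  }
  stop("could not complete orthonormal basis")
}

#' Recursive self-tuning spectral clustering
#'
#' Applies [quality_curve()] and the chosen discretization at the root, then
#' recursively to the submatrix induced by each recovered cluster, down to
#' `max_tiers` tiers. A cluster is split only when it has at least
#' `min_cluster_size` nodes and the quality of its best split reaches
#' `quality_floor`; otherwise it is carried down unchanged. Nodes isolated
#' within a submatrix (zero degree there) are split off as singleton leaves
#' before the spectral step.
#'
#' @param w symmetric non-negative connectivity matrix.
#' @param max_tiers number of recursion tiers (default 3).
#' @param min_cluster_size smallest cluster eligible for further splitting
#'   (default 4).
#' @param c_max largest candidate group number per split (default 8, capped at
#'   cluster size).
#' @param quality_floor minimum quality for a split to be accepted
#'   (default 0.5).
#' @param method `"rotation"` ([assign_clusters()] on the aligned embedding) or
#'   `"svd"` ([discretize_svd()]).
#' @return a `cluster_tree` whose clusters carry their quality curves.
#' @export
cluster_recursive <- function(w, max_tiers = 3L, min_cluster_size = 4L,
                              c_max = 8L, quality_floor = 0.5,
                              method = c("rotation", "svd"), select_tol = 1e-6) {
  method <- match.arg(method)
  w <- .validate_conn_matrix(w)
  stopifnot(max_tiers >= 1L)
  n <- nrow(w)
  tiers <- list(list(new_cluster(seq_len(n))))
  for (t in seq_len(max_tiers)) {
    prev <- tiers[[t]]
    cur <- list()
    for (pi in seq_along(prev)) {
      members <- prev[[pi]]$members
      parts <- .split_cluster(w, members, min_cluster_size, c_max,
                              quality_floor, method, select_tol)
      if (is.null(parts)) {
        cur <- c(cur, list(new_cluster(members, parent = pi, carried = TRUE)))
      } else {
        cur <- c(cur, lapply(parts$clusters, function(mm)
          new_cluster(mm, parent = pi, quality = parts$quality)))
      }
    }
    tiers[[t + 1L]] <- cur
  }
  validate_cluster_tree(new_cluster_tree(tiers, n))
}

# Attempt one split; NULL when the cluster is kept whole.
.split_cluster <- function(w, members, min_cluster_size, c_max, quality_floor,
                           method, select_tol = 1e-6) {
  if (length(members) < max(2L, min_cluster_size)) return(NULL)
  sub <- w[members, members, drop = FALSE]
  deg <- rowSums(sub)
  isolated <- which(deg == 0)
  core <- setdiff(seq_along(members), isolated)
  if (length(core) < max(2L, min_cluster_size)) return(NULL)
  subc <- sub[core, core, drop = FALSE]
  qc <- tryCatch(quality_curve(subc, c_max = min(c_max, length(core) - 1L),
                               select_tol = select_tol),
                 error = function(e) NULL)
  if (is.null(qc)) return(NULL)
  qsel <- qc$qualities[match(qc$selected, qc$group_numbers)]
  if (qsel < quality_floor) return(NULL)
  labels <- if (method == "rotation") {
    assign_clusters(qc$Z[[match(qc$selected, qc$group_numbers)]])
  } else {
    ev <- top_eigenvectors(normalized_laplacian(subc), qc$selected)
    as.integer(discretize_svd(ev))
  }
  groups <- split(members[core], labels)
  groups <- groups[order(vapply(groups, min, numeric(1)))] # stable order
  clusters <- c(unname(groups), lapply(members[isolated], identity))
  if (length(clusters) < 2L) return(NULL)
  list(clusters = clusters, quality = qc)
}

#' Clustering quality versus weight-shuffled null networks
#'
#' Compares the selected-split quality `q(C*)` of the input with its
#' distribution over `n_rand` weight-shuffled nulls ([shuffle_null()]) and
#' reports the empirical percentile of the observed quality. A structured
#' network should sit in the extreme upper tail of its null ensemble.
#'
#' @param w symmetric non-negative connectivity matrix.
#' @param n_rand number of null networks (default 100).
#' @param seed integer seed for the null ensemble.
#' @param c_max largest candidate group number (default 8).
#' @return list with `q_observed`, `selected`, `q_null` (vector), and
#'   `percentile` (in \[0, 100\]).
#' @export
null_quality_comparison <- function(w, n_rand = 100L, seed = 1L, c_max = 8L) {
  stopifnot(n_rand >= 1L)
  w <- .validate_conn_matrix(w)
  qc <- quality_curve(w, c_max = c_max)
  q_obs <- qc$qualities[match(qc$selected, qc$group_numbers)]
  set.seed(seed)
  q_null <- vapply(seq_len(n_rand), function(r) {
    null <- shuffle_null(w, seed = NULL)
    deg <- rowSums(null)
    if (any(deg == 0)) { # drop isolates the shuffle may create
      keep <- deg > 0
      null <- null[keep, keep, drop = FALSE]
      if (nrow(null) < 3L) return(NA_real_)
    }
    nq <- tryCatch(quality_curve(null, c_max = min(c_max, nrow(null))),
                   error = function(e) NULL)
    if (is.null(nq)) return(NA_real_)
    nq$qualities[match(nq$selected, nq$group_numbers)]
  }, numeric(1))
  q_null <- q_null[!is.na(q_null)]
  list(q_observed = q_obs, selected = qc$selected, q_null = q_null,
       percentile = 100 * mean(q_null < q_obs))
}
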