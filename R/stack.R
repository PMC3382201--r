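#' Multi-subject connectivity stack
#'
#' Container for a cohort of symmetric, non-negative, zero-diagonal N x N
#' connectivity matrices (one per subject) plus region-of-interest labels.
#'
#' @param matrices list of S numeric N x N matrices.
#' @param roi_labels character vector of N region labels. Defaults to
#'   `ROI_001 ...`.
#' @param subject_ids character vector of S subject identifiers. Defaults to
#'   `subj_01 ...`.
#' @return an object of class `subject_stack`.
#' @export
subject_stack <- function(matrices, roi_labels = NULL, subject_ids = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  n <- nrow(matrices[[1L]])
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI_%03d", seq_len(n))
  if (is.null(subject_ids)) subject_ids <- sprintf("subj_%02d", seq_along(matrices))
  x <- structure(list(matrices = matrices,
                      roi_labels = as.character(roi_labels),
                      subject_ids = as.character(subject_ids)),
                 class = "subject_stack")
  validate_subject_stack(x)
}

#' Validate a subject stack
#'
#' Checks that all matrices are square of a common size, symmetric within a
#' relative tolerance of 1e-9, non-negative, free of NA/NaN, and have an exactly
#' zero diagonal; symmetry within tolerance is enforced by averaging.
#'
#' @param x a `subject_stack`.
#' @return the validated (and exactly symmetrized) stack.
#' @export
validate_subject_stack <- function(x) {
  stopifnot(inherits(x, "subject_stack"))
  n <- nrow(x$matrices[[1L]])
  if (length(x$roi_labels) != n) stop("label count must equal matrix dimension")
  if (length(x$subject_ids) != length(x$matrices))
    stop("subject id count must equal number of matrices")
  x$matrices <- lapply(x$matrices, function(m) .validate_conn_matrix(m, n))
  x
}

# Shared matrix validation: square, no NA, non-negative, symmetric within
# 1e-9 relative tolerance (then symmetrized by averaging), zero diagonal.
.validate_conn_matrix <- function(m, n = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("format error: matrix is not square")
  if (!is.null(n) && nrow(m) != n) stop("matrices in a stack must share dimensions")
  if (anyNA(m)) stop("domain error: matrix contains NA/NaN entries")
  if (any(m < 0)) stop("domain error: matrix contains negative weights")
  scale <- max(abs(m), 1e-300)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9 * scale)
    stop(sprintf("symmetry error: max asymmetry %.3g exceeds 1e-9 relative tolerance", asym))
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    warning("nonzero diagonal entries forced to 0")
    diag(m) <- 0
  }
  unname(m)
}

#' @export
print.subject_stack <- function(x, ...) {
  n <- nrow(x$matrices[[1L]])
  nz <- vapply(x$matrices, function(m) sum(m[upper.tri(m)] > 0), integer(1))
  cat(sprintf("subject_stack: %d subjects x %d nodes; %d-%d nonzero upper-triangle edges/subject\n",
              length(x$matrices), n, min(nz), max(nz)))
  invisible(x)
}

#' Number of nodes / subjects in a stack
#' @param stack a `subject_stack`.
#' @return integer.
#' @export
n_nodes <- function(stack) nrow(stack$matrices[[1L]])

#' @rdname n_nodes
#' @export
n_subjects <- function(stack) length(stack$matrices)

#' Entrywise mean connectivity matrix of a cohort
#' @param stack a `subject_stack`.
#' @return symmetric N x N matrix, the entrywise mean across subjects.
#' @export
average_matrix <- function(stack) {
  Reduce(`+`, stack$matrices) / length(stack$matrices)
}
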