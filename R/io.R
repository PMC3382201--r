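#' Read a connectivity matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited square numeric text. The matrix must
#' be non-negative and symmetric within a relative tolerance of 1e-9 (it is
#' then symmetrized by averaging); nonzero diagonal entries are forced to zero
#' with a warning.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   strip.white = TRUE))
  storage.mode(m) <- "double"
  .validate_conn_matrix(m)
}

#' Write a connectivity matrix as tab-delimited text
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param digits significant digits written (default 17, lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = 17L) {
  lines <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a cohort directory
#'
#' A cohort directory holds one matrix file per subject
#' (`<subject_id>.tsv`), a `subjects.txt` listing subject ids in order, and a
#' `roi_labels.tsv` ROI table (see [read_roi_table()]).
#'
#' @param stack a [subject_stack()].
#' @param dir directory path (created if missing).
#' @return `write_cohort`: `dir` invisibly; `read_cohort`: a `subject_stack`.
#' @export
write_cohort <- function(stack, dir) {
  stack <- validate_subject_stack(stack)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(stack$subject_ids, file.path(dir, "subjects.txt"))
  hemi <- .hemisphere_from_label(stack$roi_labels)
  utils::write.table(
    data.frame(index = seq_along(stack$roi_labels), name = stack$roi_labels,
               hemisphere = hemi),
    file.path(dir, "roi_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(stack$matrices))
    write_matrix(stack$matrices[[k]], file.path(dir, paste0(stack$subject_ids[k], ".tsv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ids <- readLines(file.path(dir, "subjects.txt"))
  rois <- read_roi_table(file.path(dir, "roi_labels.tsv"))
  mats <- lapply(ids, function(id) read_matrix(file.path(dir, paste0(id, ".tsv"))))
  subject_stack(mats, roi_labels = rois$name, subject_ids = ids)
}

#' Read a region-of-interest table
#'
#' Tab-separated table with columns `index` (1-based, unique, contiguous),
#' `name`, and `hemisphere` (`left`, `right`, or `none`).
#'
#' @param path file path.
#' @return data.frame with those three columns, ordered by index.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("index", "name", "hemisphere") %in% names(tab)))
  tab <- tab[order(tab$index), , drop = FALSE]
  if (!identical(as.integer(tab$index), seq_len(nrow(tab))))
    stop("ROI indices must be unique and contiguous from 1")
  if (!all(tab$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be one of left/right/none")
  rownames(tab) <- NULL
  tab
}

.hemisphere_from_label <- function(labels) {
  ifelse(grepl("_L$", labels), "left",
         ifelse(grepl("_R$", labels), "right", "none"))
}

#' Restrict a cohort to a subset of regions
#'
#' Removes the named regions (for example the 26 cerebellar and vermis
#' structures of a 116-region whole-brain parcellation, leaving the 90
#' cerebral regions) from every subject matrix and from the label list,
#' preserving the original order of the retained regions.
#'
#' @param stack a [subject_stack()].
#' @param roi_table data.frame as returned by [read_roi_table()]; its `name`
#'   column must match `stack$roi_labels`.
#' @param exclude_names character vector of region names to drop.
#' @return the restricted `subject_stack`.
#' @export
filter_rois <- function(stack, roi_table, exclude_names) {
  stack <- validate_subject_stack(stack)
  if (!identical(roi_table$name, stack$roi_labels))
    stop("ROI table does not match the stack's labels")
  unknown <- setdiff(exclude_names, roi_table$name)
  if (length(unknown))
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  keep <- !(stack$roi_labels %in% exclude_names)
  subject_stack(lapply(stack$matrices, function(m) m[keep, keep, drop = FALSE]),
                roi_labels = stack$roi_labels[keep],
                subject_ids = stack$subject_ids)
}

#' Export a hierarchy tree as a Newick string / file
#'
#' Leaf names are the member labels joined by `|`; internal nodes are
#' unlabeled; each tier contributes one nesting level. Clusters carried down
#' unsplit are collapsed, so the exported topology reflects only genuine
#' splits.
#'
#' @param tree a `cluster_tree`.
#' @param roi_labels character vector of node labels (length `tree$n_nodes`).
#' @param path optional output file; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_tree_newick <- function(tree, roi_labels = NULL, path = NULL) {
  validate_cluster_tree(tree)
  if (tree$n_nodes < 1L) stop("empty tree")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI_%03d", seq_len(tree$n_nodes))
  stopifnot(length(roi_labels) == tree$n_nodes)
  rec <- function(tier, idx) {
    kids <- .tree_children(tree, tier, idx)
    if (length(kids) == 1L && tree$tiers[[tier + 2L]][[kids]]$carried)
      return(rec(tier + 1L, kids))
    if (length(kids) == 0L) {
      members <- tree$tiers[[tier + 1L]][[idx]]$members
      lab <- paste(roi_labels[members], collapse = "|")
      # multi-member leaf clusters are set off as their own group
      return(if (length(members) > 1L) paste0("(", lab, ")") else lab)
    }
    paste0("(", paste(vapply(kids, function(k) rec(tier + 1L, k), character(1)),
                      collapse = ","), ")")
  }
  nwk <- paste0(rec(0L, 1L), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Export the upper triangle of a matrix as an edge list
#'
#' Writes `node_i`, `node_j`, `weight` (1-based indices, `i < j`, nonzero
#' weights only) as tab-separated text for consumption by graph tools.
#'
#' @param m symmetric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(m, path) {
  m <- .validate_conn_matrix(m)
  ij <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  df <- data.frame(node_i = ij[, 1L], node_j = ij[, 2L],
                   weight = m[ij])
  df <- df[order(df$node_i, df$node_j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
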