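#' Hierarchical clustering of a phenotype profile matrix
#'
#' Agglomerative clustering of cell lines (rows) or probes/features
#' (columns) of a fold-change matrix, the dual-axis view behind profile
#' heatmaps. Fold changes are log2-transformed by default, which puts
#' turn-on and turn-off responses on a symmetric scale. The leaf order is
#' canonicalized by a recursive smallest-leaf-index-first traversal so
#' identical inputs always order identically, whatever the merge order.
#'
#' @param data A feature matrix from [build_feature_matrix()].
#' @param axis `"lines"` (cluster rows) or `"probes"` (cluster feature
#'   columns).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param log2 Log2-transform folds before computing distances.
#' @return A `pheno_dendro`: list with the `hclust` object, `labels`,
#'   `leaf_order` (canonical), `merges` tibble `(a, b, height)` (negative
#'   entries are leaves, positive are prior merges), `axis` and the
#'   origin labels when `axis = "lines"`.
#' @export
hierarchical_cluster <- function(data, axis = c("lines", "probes"),
                                 metric = "euclidean",
                                 linkage = "average", log2 = TRUE) {
  axis <- match.arg(axis)
  x <- feature_matrix_of(data)
  if (log2) x <- base::log2(x)
  if (axis == "probes") x <- t(x)
  if (nrow(x) < 2) abort("need >= 2 items on the clustered axis")
  if (any(!is.finite(x))) abort("matrix contains missing/non-finite values")
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  structure(
    list(hclust = hc,
         labels = hc$labels,
         leaf_order = canonical_leaf_order(hc$merge),
         merges = tibble(a = hc$merge[, 1], b = hc$merge[, 2],
                         height = hc$height),
         axis = axis,
         origins = if (axis == "lines") {
           data$origin[match(hc$labels, data$line_id)]
         } else NULL,
         metric = metric, linkage = linkage),
    class = "pheno_dendro"
  )
}

# canonical leaf order: at every merge node visit the child whose subtree
# contains the smallest leaf index first
canonical_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  orders <- vector("list", nrow(merge))
  child_order <- function(ch) if (ch < 0) -ch else orders[[ch]]
  for (k in seq_len(nrow(merge))) {
    left <- child_order(merge[k, 1]); right <- child_order(merge[k, 2])
    orders[[k]] <- if (min(left) <= min(right)) c(left, right)
    else c(right, left)
  }
  if (n == 1L) 1L else orders[[nrow(merge)]]
}

#' @export
print.pheno_dendro <- function(x, ...) {
  cat(sprintf("<pheno_dendro> %d %s, %s distance, %s linkage\n",
              length(x$labels), x$axis, x$metric, x$linkage))
  invisible(x)
}

#' Cut a dendrogram and score cluster purity against origin labels
#'
#' Cuts the tree into `k` groups and reports the fraction of items whose
#' cluster's majority origin matches their own:
#' purity = (sum over clusters of the majority-origin count) / n.
#' Purity is 1 for a cut that reproduces the origin partition, and
#' degenerately 1 when every cluster is a singleton, so it is a
#' diagnostic to compare against permuted labels, not an absolute score.
#'
#' @param dendro A `pheno_dendro` over lines, or an integer/character
#'   vector of cluster assignments.
#' @param k Number of clusters to cut (ignored when assignments given).
#' @param origins Origin labels (taken from the dendrogram if available).
#' @return A list with `purity`, `k` and the `assignments`.
#' @export
origin_purity <- function(dendro, k = 9, origins = NULL) {
  if (inherits(dendro, "pheno_dendro")) {
    if (k < 1 || k > length(dendro$labels)) {
      abort("`k` must be in [1, number of leaves]")
    }
    assignments <- stats::cutree(dendro$hclust, k = k)
    origins <- origins %||% dendro$origins
  } else {
    assignments <- dendro
    k <- dplyr::n_distinct(assignments)
  }
  if (is.null(origins) || length(origins) != length(assignments)) {
    abort("origin labels of matching length are required")
  }
  counts <- table(assignments, origins)
  purity <- sum(apply(counts, 1, max)) / length(assignments)
  list(purity = purity, k = k, assignments = assignments)
}

#' Serialize a dendrogram as a Newick tree
#'
#' @param dendro A `pheno_dendro`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "pheno_dendro"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the `ape` package")
  }
  phy <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Leaf orders of both axes as a tibble
#'
#' @param row_dendro,col_dendro `pheno_dendro` objects for lines and
#'   probes.
#' @return Tibble `(axis, position, label)`.
#' @export
leaf_orders <- function(row_dendro, col_dendro) {
  dplyr::bind_rows(
    tibble(axis = row_dendro$axis,
           position = seq_along(row_dendro$leaf_order),
           label = row_dendro$labels[row_dendro$leaf_order]),
    tibble(axis = col_dendro$axis,
           position = seq_along(col_dendro$leaf_order),
           label = col_dendro$labels[col_dendro$leaf_order])
  )
}
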