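# Distance computation and the two agglomerative engines (Ward, complete
# linkage) that cross-clustering combines, plus deterministic tree cutting.

# An "expression matrix" here is any numeric items-by-features matrix with
# unique row identifiers; items to be clustered are rows.
validate_expression_matrix <- function(x, min_items = 3L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("input must be a numeric matrix (items in rows)")
  if (nrow(x) < min_items)
    stop_input("at least %d items (rows) are required, got %d",
               min_items, nrow(x))
  if (ncol(x) < 1L)
    stop_input("at least one feature (column) is required")
  bad <- which(!stats::complete.cases(x) | apply(x, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop_input("missing or non-finite values in row(s): %s",
               paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("item_", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop_input("duplicate item identifiers: %s",
               paste(utils::head(unique(rownames(x)[duplicated(rownames(x))]), 5L),
                     collapse = ", "))
  x
}

#' Pairwise distances between items
#'
#' Computes all pairwise Euclidean or Chebychev (maximum-coordinate)
#' distances between the rows of a numeric matrix.
#'
#' @param x Numeric matrix, items in rows (at least 3) with unique row names
#'   (assigned automatically when absent).  Missing values are rejected.
#' @param metric `"euclidean"` (root of summed squared coordinate
#'   differences) or `"chebychev"` (maximum absolute coordinate difference).
#' @return A [stats::dist] object with attribute `metric` recording the
#'   metric name.
#' @examples
#' x <- rbind(a = c(0, 0), b = c(3, 4), c = c(1, 2))
#' as.matrix(pairwise_distances(x))["a", "b"]   # 5
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "chebychev")) {
  metric <- tryCatch(match.arg(metric),
                     error = function(e) stop_config(
                       "unknown metric '%s': use 'euclidean' or 'chebychev'",
                       as.character(metric)[1L]))
  x <- validate_expression_matrix(x)
  d <- stats::dist(x, method = if (metric == "chebychev") "maximum" else "euclidean")
  attr(d, "metric") <- metric
  d
}

as_dist_checked <- function(d) {
  if (inherits(d, "dist")) {
    if (anyNA(d) || any(!is.finite(d)))
      stop_input("distance object contains missing or non-finite values")
    if (any(d < 0)) stop_input("distances must be non-negative")
    return(d)
  }
  if (is.matrix(d) && is.numeric(d)) {
    if (nrow(d) != ncol(d)) stop_input("distance matrix must be square")
    if (anyNA(d) || any(!is.finite(d)))
      stop_input("distance matrix contains missing or non-finite values")
    if (max(abs(d - t(d))) > 1e-8)
      stop_input("distance matrix must be symmetric")
    if (any(diag(d) != 0))
      stop_input("distance matrix must have a zero diagonal")
    if (any(d < 0)) stop_input("distances must be non-negative")
    return(stats::as.dist(d))
  }
  stop_input("expected a 'dist' object or a symmetric numeric matrix")
}

#' Agglomerative clustering tree (Ward or complete linkage)
#'
#' Builds the merge tree over items from a distance object.  `"ward"` uses
#' the minimum-variance criterion with heights on the original distance
#' scale (the `ward.D2` convention: for Euclidean input the squared merge
#' height equals twice the increase in within-cluster sum of squared
#' errors); `"complete"` defines inter-cluster distance as the maximum
#' pairwise distance between members.
#'
#' @param d A [stats::dist] object or symmetric numeric matrix of pairwise
#'   distances over at least 2 items.
#' @param method `"ward"` or `"complete"`.
#' @return An [stats::hclust] tree.
#' @seealso [cut_tree()], [cross_cluster()]
#' @export
linkage <- function(d, method = c("ward", "complete")) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_config(
                       "unknown linkage method '%s': use 'ward' or 'complete'",
                       as.character(method)[1L]))
  d <- as_dist_checked(d)
  if (attr(d, "Size") < 2L)
    stop_input("at least 2 items are required to build a tree")
  stats::hclust(d, method = if (method == "ward") "ward.D2" else "complete")
}

#' Cut a clustering tree into k clusters
#'
#' Cuts an agglomerative tree at the level producing exactly `k` nonempty
#' clusters.  Cluster labels are assigned deterministically in order of
#' first appearance along the input item order, so repeated cuts of the
#' same tree are reproducible and cuts at `k` and `k + 1` are nested.
#'
#' @param tree An [stats::hclust] tree (e.g. from [linkage()]).
#' @param k Number of clusters, between 1 and the number of items.
#' @return Named integer vector of cluster labels in `1..k`.
#' @export
cut_tree <- function(tree, k) {
  if (!inherits(tree, "hclust")) stop_input("'tree' must be an hclust tree")
  n <- length(tree$order)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1L || k > n)
    stop_input("k must be a single integer in [1, %d], got %s", n,
               paste(k, collapse = ","))
  relabel_first_appearance(stats::cutree(tree, k = as.integer(k)))
}

#' Write a merge tree as a plain-text table
#'
#' Serialises an agglomerative tree to a TSV with columns `left`, `right`,
#' `height` and `size` (cluster size after the merge).  Negative values in
#' `left`/`right` index original items, positive values index earlier
#' merges — the usual `hclust` merge-table convention.
#'
#' @param tree An [stats::hclust] tree.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_merge_table <- function(tree, path) {
  if (!inherits(tree, "hclust")) stop_input("'tree' must be an hclust tree")
  m <- tree$merge
  sizes <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    sizes[i] <- sum(ifelse(m[i, ] < 0, 1, sizes[pmax(m[i, ], 1)]))
  }
  tab <- data.frame(left = m[, 1], right = m[, 2],
                    height = tree$height, size = as.integer(sizes))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
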