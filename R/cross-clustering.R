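# The cross-clustering consensus machinery: contingency tables between a
# Ward cut and a finer complete-linkage cut, exact maximisation of the
# diagonal sum over column permutations (a linear assignment problem), and
# the scan over cut-level pairs that picks the maximum-overlap consensus.

validate_partition <- function(p, arg = "partition") {
  if (!is.numeric(p) || length(p) < 1L)
    stop_input("'%s' must be a non-empty integer label vector", arg)
  if (anyNA(p) || !is_whole(p) || any(p < 1))
    stop_input("'%s' must contain positive integer labels only", arg)
  p <- stats::setNames(as.integer(round(p)), names(p))
  k <- max(p)
  if (!all(seq_len(k) %in% p))
    stop_input("'%s' must use every label in 1..%d (no empty clusters)", arg, k)
  p
}

#' Cross-tabulate two partitions
#'
#' Builds the contingency table `a` whose entry `a[r, s]` counts the items
#' assigned simultaneously to cluster `r` of `p_w` and cluster `s` of `p_c`.
#'
#' @param p_w,p_c Integer label vectors of equal length with labels `1..k`
#'   (every label present).  In cross-clustering `p_w` is the Ward cut and
#'   `p_c` the (finer) complete-linkage cut.
#' @return Integer matrix with `max(p_w)` rows and `max(p_c)` columns;
#'   entries sum to the number of items, row/column margins equal the
#'   cluster sizes.
#' @export
build_contingency <- function(p_w, p_c) {
  p_w <- validate_partition(p_w, "p_w")
  p_c <- validate_partition(p_c, "p_c")
  if (length(p_w) != length(p_c))
    stop_input("partitions have different lengths (%d vs %d)",
               length(p_w), length(p_c))
  r <- max(p_w); s <- max(p_c)
  a <- tabulate(p_w + (p_c - 1L) * r, nbins = r * s)
  a <- matrix(as.integer(a), nrow = r, ncol = s,
              dimnames = list(w = seq_len(r), c = seq_len(s)))
  a
}

#' Maximum diagonal overlap of a contingency table
#'
#' Finds the column permutation of a nonnegative contingency table that
#' maximises the diagonal sum — the maximum overlap (MO) between the two
#' partitions the table cross-tabulates.  Solved exactly as a linear
#' assignment problem on the zero-padded square negated table, which is
#' equivalent to exhaustive search over injective row-to-column matchings.
#'
#' @param a Nonnegative integer matrix (rows: clusters of one partition,
#'   columns: clusters of the other).  Any shape is accepted; `min(r, s)`
#'   pairs are matched.
#' @return An object of class `"overlap_assignment"`: a list with `mo`
#'   (the maximal diagonal sum, an integer count of matched items) and
#'   `col_for_row` (for each row, the matched column; `NA` for rows left
#'   unmatched when there are more rows than columns).
#' @examples
#' max_trace_overlap(rbind(c(3, 0, 1), c(0, 2, 0)))$mo   # 5
#' @export
max_trace_overlap <- function(a) {
  if (!is.matrix(a) || !is.numeric(a))
    stop_input("'a' must be a numeric matrix")
  if (anyNA(a) || any(!is.finite(a)))
    stop_input("'a' contains missing or non-finite entries")
  if (any(a < 0)) stop_input("'a' must be nonnegative")
  if (!is_whole(a)) stop_input("'a' must contain integer counts")
  r <- nrow(a); s <- ncol(a)
  if (r <= s) {
    col_for_row <- solve_assignment_cpp(-a)
  } else {
    # more rows than columns: match every column to a distinct row instead
    row_of_col <- solve_assignment_cpp(-t(a))
    col_for_row <- rep(NA_integer_, r)
    col_for_row[row_of_col] <- seq_len(s)
  }
  matched <- !is.na(col_for_row)
  mo <- sum(a[cbind(which(matched), col_for_row[matched])])
  structure(list(mo = as.integer(mo), col_for_row = col_for_row),
            class = "overlap_assignment")
}

#' Consensus partial partition from two matched partitions
#'
#' Given two partitions of the same items and an optimal row-to-column
#' matching of their contingency table, assigns each item to a consensus
#' cluster when both partitions agree under the matching, and labels it 0
#' (outlier) otherwise.  Empty consensus clusters are dropped and labels
#' renumbered contiguously in order of first appearance.
#'
#' @inheritParams build_contingency
#' @param asg An `"overlap_assignment"` from
#'   `max_trace_overlap(build_contingency(p_w, p_c))`.
#' @return Integer vector of labels: `0` marks outliers, `1..K` the
#'   consensus clusters.  The number of non-zero labels equals `asg$mo`.
#' @export
consensus_partition <- function(p_w, p_c, asg) {
  p_w <- validate_partition(p_w, "p_w")
  p_c <- validate_partition(p_c, "p_c")
  if (length(p_w) != length(p_c))
    stop_input("partitions have different lengths (%d vs %d)",
               length(p_w), length(p_c))
  if (!inherits(asg, "overlap_assignment"))
    stop_input("'asg' must come from max_trace_overlap()")
  cfr <- asg$col_for_row
  if (length(cfr) != max(p_w) ||
      any(cfr[!is.na(cfr)] > max(p_c)) || any(cfr[!is.na(cfr)] < 1))
    stop_internal("assignment is inconsistent with the partitions")
  labels <- integer(length(p_w))
  for (r in seq_along(cfr)) {
    if (!is.na(cfr[r])) labels[p_w == r & p_c == cfr[r]] <- r
  }
  if (sum(labels > 0L) != asg$mo)
    stop_internal("consensus size %d does not match mo = %d",
                  sum(labels > 0L), asg$mo)
  pos <- labels > 0L
  labels[pos] <- match(labels[pos], unique(labels[pos]))
  names(labels) <- names(p_w)
  labels
}

#' Cross-clustering: partial clustering with automatic cluster-count choice
#'
#' Runs the full cross-clustering scan.  One Ward tree and one
#' complete-linkage tree are built once; for every Ward cut into `n_W`
#' clusters (`n_W` in `[kw_min, kw_max]`) crossed with every finer
#' complete-linkage cut into `n_C` clusters (`n_C` in
#' `[kw_min + 1, kc_max]`, `n_C > n_W`) the maximum contingency-table
#' overlap MO is computed.  The pair maximising MO — ties broken towards
#' the smallest `n_W`, then the smallest `n_C` — determines the estimated
#' number of clusters (the Ward count) and the consensus partial
#' partition; unmatched items are reported as outliers (label 0).  The
#' scan is fully deterministic.
#'
#' @param x Numeric items-by-features matrix (ignored when `d` is given).
#' @param d Optional precomputed distances ([stats::dist] or symmetric
#'   matrix); when supplied, `metric` and `standardize` are not used.
#' @param kw_min,kw_max Inclusive Ward scan range; defaults 2 and 19.
#' @param kc_max Maximum complete-linkage cluster count; default 20.  Must
#'   satisfy `2 <= kw_min <= kw_max < kc_max <= n - 1`.  A high `kc_max`
#'   isolates items unlikely to belong to any cluster.
#' @param metric Distance metric for `x`; see [pairwise_distances()].
#' @param standardize Scale each row of `x` to mean 0, variance 1 before
#'   computing distances (default `FALSE`).
#' @return An object of class `"cc_result"`: list with elements
#'   `n_w_star`, `n_c_star` (selected cut pair), `mo` (overlap at the
#'   optimum), `mo_matrix` (MO for every scanned pair, `NA` where
#'   `n_C <= n_W`), `labels` (named integer vector, 0 = outlier), `k`
#'   (number of nonempty consensus clusters), `outlier_ids`, `n_items`,
#'   `params`, and `single_cluster_advisory` (`TRUE` when the optimum sits
#'   on the `n_W = kw_min = 2` boundary with one consensus cluster holding
#'   more than 90% of matched items — a hint that the data may not support
#'   partitioning).
#' @references The combination rationale: Ward builds well-separated
#'   clusters and estimates their number reliably; complete linkage
#'   isolates outliers into small clusters.  Crossing a coarse Ward cut
#'   with a finer complete-linkage cut therefore recovers the cluster
#'   cores while shedding noise items.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
#' res <- cross_cluster(x, kw_min = 2, kw_max = 4, kc_max = 8)
#' res$k
#' @export
cross_cluster <- function(x = NULL, d = NULL,
                          kw_min = 2L, kw_max = 19L, kc_max = 20L,
                          metric = c("euclidean", "chebychev"),
                          standardize = FALSE) {
  metric <- tryCatch(match.arg(metric),
                     error = function(e) stop_config(
                       "unknown metric '%s'", as.character(metric)[1L]))
  if (is.null(d)) {
    if (is.null(x)) stop_input("supply either 'x' or 'd'")
    x <- validate_expression_matrix(x)
    if (standardize) x <- standardize_rows(x)
    d <- pairwise_distances(x, metric)
  } else {
    d <- as_dist_checked(d)
  }
  n <- attr(d, "Size")
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- paste0("item_", seq_len(n))

  for (nm in c("kw_min", "kw_max", "kc_max")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      stop_config("'%s' must be a single integer", nm)
  }
  kw_min <- as.integer(kw_min); kw_max <- as.integer(kw_max)
  kc_max <- as.integer(kc_max)
  if (kw_min < 2L) stop_config("kw_min must be >= 2 (violated: kw_min = %d)", kw_min)
  if (kw_max < kw_min)
    stop_config("kw_max must be >= kw_min (violated: kw_max = %d < kw_min = %d)",
                kw_max, kw_min)
  if (kc_max <= kw_max)
    stop_config("kc_max must be > kw_max (violated: kc_max = %d <= kw_max = %d)",
                kc_max, kw_max)
  if (kc_max > n - 1L)
    stop_config("kc_max must be <= n_items - 1 (violated: kc_max = %d > %d)",
                kc_max, n - 1L)

  tree_w <- linkage(d, "ward")
  tree_c <- linkage(d, "complete")
  kw_vals <- kw_min:kw_max
  kc_vals <- (kw_min + 1L):kc_max
  cuts_w <- vapply(kw_vals, function(k) cut_tree(tree_w, k), integer(n))
  cuts_c <- vapply(kc_vals, function(k) cut_tree(tree_c, k), integer(n))

  mo_matrix <- matrix(NA_real_, length(kw_vals), length(kc_vals),
                      dimnames = list(n_w = kw_vals, n_c = kc_vals))
  best <- list(mo = -1L)
  for (i in seq_along(kw_vals)) {
    pw <- cuts_w[, i]
    for (j in seq_along(kc_vals)) {
      if (kc_vals[j] <= kw_vals[i]) next
      a <- tabulate(pw + (cuts_c[, j] - 1L) * kw_vals[i],
                    nbins = kw_vals[i] * kc_vals[j])
      dim(a) <- c(kw_vals[i], kc_vals[j])
      asg <- max_trace_overlap(a)
      mo_matrix[i, j] <- asg$mo
      if (asg$mo > best$mo)
        best <- list(mo = asg$mo, i = i, j = j, asg = asg)
    }
  }

  pw <- cuts_w[, best$i]
  pc <- cuts_c[, best$j]
  names(pw) <- names(pc) <- ids
  labels <- consensus_partition(pw, pc, best$asg)
  k_final <- length(unique(labels[labels > 0L]))
  sizes <- tabulate(labels[labels > 0L])
  advisory <- kw_vals[best$i] == kw_min && kw_min == 2L &&
    length(sizes) > 0L && max(sizes) > 0.9 * best$mo

  structure(list(
    n_w_star = kw_vals[best$i],
    n_c_star = kc_vals[best$j],
    mo = best$mo,
    mo_matrix = mo_matrix,
    labels = labels,
    k = k_final,
    outlier_ids = ids[labels == 0L],
    n_items = n,
    params = list(kw_min = kw_min, kw_max = kw_max, kc_max = kc_max,
                  metric = metric, standardize = isTRUE(standardize)),
    single_cluster_advisory = advisory
  ), class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat("Cross-clustering result\n")
  cat(sprintf("  items: %d   selected pair: n_W = %d, n_C = %d (MO = %d)\n",
              x$n_items, x$n_w_star, x$n_c_star, x$mo))
  cat(sprintf("  consensus clusters: %d   outliers: %d\n",
              x$k, length(x$outlier_ids)))
  if (isTRUE(x$single_cluster_advisory))
    cat("  advisory: overlap maximised on the n_W = 2 boundary with one\n",
        " dominant cluster - the data may not support partitioning\n", sep = "")
  invisible(x)
}

standardize_rows <- function(x) {
  sds <- apply(x, 1L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero))
    stop_input("cannot standardize constant row(s): %s",
               paste(utils::head(rownames(x)[zero], 5L), collapse = ", "))
  t(scale(t(x)))[, , drop = FALSE]
}
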