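# Cluster-validity indices used to benchmark partial clusterings: the
# adjusted Rand index (with an outliers-as-one-cluster convention),
# majority-mapping confusion measures, information gain, silhouette widths
# and average-silhouette-width selection of k.

check_label_pair <- function(p1, p2) {
  if (!is.numeric(p1) || !is.numeric(p2))
    stop_input("label vectors must be numeric")
  if (length(p1) != length(p2))
    stop_input("label vectors have different lengths (%d vs %d)",
               length(p1), length(p2))
  if (anyNA(p1) || anyNA(p2)) stop_input("label vectors must not contain NA")
  list(as.integer(p1), as.integer(p2))
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions of the same items,
#' corrected for chance under the permutation model: 1 for identical
#' partitions, expectation 0 for independent ones, negative values for
#' less-than-chance agreement.
#'
#' Partial clusterings mark outliers with label 0.  With
#' `outliers_as_cluster = TRUE` (the default) label 0 is recoded as one
#' ordinary extra cluster, so partial and complete clusterings remain
#' comparable; with `FALSE`, items labeled 0 in either vector are dropped
#' before computing the index.
#'
#' @param p1,p2 Integer label vectors of equal length (0 allowed as the
#'   outlier sentinel).
#' @param outliers_as_cluster Treat label 0 as its own cluster (default)
#'   rather than excluding those items.
#' @return A single number in `[-1, 1]`.
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2))   # -0.5
#' @export
adjusted_rand <- function(p1, p2, outliers_as_cluster = TRUE) {
  ps <- check_label_pair(p1, p2)
  p1 <- ps[[1]]; p2 <- ps[[2]]
  if (!outliers_as_cluster) {
    keep <- p1 != 0L & p2 != 0L
    p1 <- p1[keep]; p2 <- p2[keep]
    if (length(p1) < 2L)
      stop_input("fewer than 2 items remain after excluding outliers")
  }
  tab <- table(p1, p2)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(p1), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial, hence identical
  (sij - expected) / denom
}

#' Majority-mapping confusion summary of a clustering
#'
#' For each true class `C`, the representative predicted cluster `X` is
#' the one containing the largest number of `C`'s items (ties broken
#' towards the lower predicted label).  Items of `C` inside `X` are true
#' positives, other items inside `X` false positives, items of `C`
#' outside `X` false negatives, and the rest true negatives.  From these,
#' per-class sensitivity, specificity, positive predictive value,
#' geometric accuracy `sqrt(sensitivity * specificity)` and the AUC of the
#' two-segment ROC through the single operating point,
#' `(sensitivity + specificity) / 2`, are derived.
#'
#' Label 0 is treated as an ordinary cluster/class (outliers as a single
#' cluster), so a partial clustering scored against a truth with an
#' outlier class compares all items.
#'
#' @param pred Predicted label vector (0 allowed).
#' @param truth True class vector (0 allowed as the outlier class); given
#'   as a factor, every level must be populated.
#' @return A `data.frame` with one row per truth class: `class`,
#'   `representative`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `acc_g`, `auc`.
#' @export
majority_confusion <- function(pred, truth) {
  if (is.factor(truth)) {
    if (any(table(truth) == 0L))
      stop_input("empty truth class: level(s) %s have no items",
                 paste(levels(truth)[table(truth) == 0L], collapse = ", "))
    truth <- as.integer(as.character(truth))
  }
  ps <- check_label_pair(pred, truth)
  pred <- ps[[1]]; truth <- ps[[2]]
  n <- length(pred)
  classes <- sort(unique(truth))
  pred_levels <- sort(unique(pred))
  out <- lapply(classes, function(cl) {
    in_class <- truth == cl
    counts <- vapply(pred_levels, function(x) sum(pred == x & in_class), 0L)
    rep_label <- pred_levels[which.max(counts)]  # first max = lowest label
    in_rep <- pred == rep_label
    tp <- sum(in_class & in_rep)
    fp <- sum(!in_class & in_rep)
    fn <- sum(in_class & !in_rep)
    tn <- n - tp - fp - fn
    sens <- tp / (tp + fn)
    spec <- if (tn + fp > 0) tn / (tn + fp) else 1
    ppv <- tp / (tp + fp)
    data.frame(class = cl, representative = rep_label,
               tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = sens, specificity = spec, ppv = ppv,
               acc_g = sqrt(sens * spec), auc = (sens + spec) / 2)
  })
  do.call(rbind, out)
}

entropy_bits <- function(x) {
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Information gain of a clustering over class labels
#'
#' Reduction in class entropy achieved by conditioning on cluster
#' membership, `H(truth) - sum_j (n_j / n) H(truth | cluster j)`, in bits.
#' Zero when clusters carry no class information, `H(truth)` when every
#' cluster is class-pure; invariant under relabeling of either vector.
#'
#' @inheritParams majority_confusion
#' @return A nonnegative number (bits).
#' @export
information_gain <- function(pred, truth) {
  ps <- check_label_pair(pred, truth)
  pred <- ps[[1]]; truth <- ps[[2]]
  n <- length(pred)
  h <- entropy_bits(truth)
  cond <- 0
  for (cl in unique(pred)) {
    idx <- pred == cl
    cond <- cond + sum(idx) / n * entropy_bits(truth[idx])
  }
  max(h - cond, 0)
}

#' Per-item silhouette widths
#'
#' The silhouette of item `i` is `(b_i - a_i) / max(a_i, b_i)`, where
#' `a_i` is its mean distance to the other members of its own cluster and
#' `b_i` the smallest mean distance to any other cluster.  Values lie in
#' `[-1, 1]`; members of singleton clusters get 0 by convention.
#'
#' @param d Pairwise distances ([stats::dist] or symmetric matrix).
#' @param p Integer label vector over the same items with `k >= 2`
#'   clusters, all nonempty.
#' @return Numeric vector of silhouette widths, one per item.
#' @export
silhouette_widths <- function(d, p) {
  d <- as_dist_checked(d)
  p <- validate_partition(p, "p")
  n <- attr(d, "Size")
  if (length(p) != n)
    stop_input("labels length (%d) does not match distance size (%d)",
               length(p), n)
  k <- max(p)
  if (k < 2L) stop_input("silhouette is undefined for k < 2")
  dm <- as.matrix(d)
  sums <- rowsum(dm, p)                 # k x n: total distance cluster -> item
  sizes <- tabulate(p, nbins = k)
  own <- sums[cbind(p, seq_len(n))]
  a <- ifelse(sizes[p] > 1L, own / (sizes[p] - 1L), 0)
  mean_to <- sums / sizes               # mean distance from each cluster
  mean_to[cbind(p, seq_len(n))] <- Inf  # mask own cluster
  b <- apply(mean_to, 2L, min)
  s <- ifelse(sizes[p] == 1L, 0,
              ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0))
  unname(s)
}

#' Select the number of clusters by average silhouette width
#'
#' Cuts a clustering tree at every `k` in `k_range`, computes the average
#' silhouette width (ASW) of each cut, and returns the `k` maximising it
#' (ties broken towards the smallest `k`).  This is the usual unsupervised
#' baseline for choosing `k` with plain hierarchical clusterings.
#'
#' @param d Pairwise distances ([stats::dist] or symmetric matrix).
#' @param tree An [stats::hclust] tree over the same items.
#' @param k_range Integer vector of candidate cluster counts, within
#'   `[2, n - 1]`.
#' @return List with `k_best` and `asw` (named vector of ASW per `k`).
#' @export
select_k_by_asw <- function(d, tree, k_range) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (length(k_range) == 0L)
    stop_config("k_range is empty: no valid k to evaluate")
  if (any(k_range != round(k_range)) || any(k_range < 2L) || any(k_range > n - 1L))
    stop_config("k_range must lie within [2, %d]", n - 1L)
  k_range <- as.integer(k_range)
  asw <- vapply(k_range, function(k) {
    mean(silhouette_widths(d, cut_tree(tree, k)))
  }, numeric(1))
  names(asw) <- k_range
  list(k_best = k_range[which.max(asw)], asw = asw)
}
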