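# Contingency tables, exact trace maximization, consensus partitions and
# the full cross-clustering scan.

test_that("contingency tables count joint memberships", {
  a <- build_contingency(c(1, 1, 2, 2), c(1, 2, 2, 3))
  expect_equal(unname(unclass(a)), rbind(c(1, 1, 0), c(0, 1, 1)),
               ignore_attr = TRUE)
  expect_equal(unname(build_contingency(1:3, 1:3)), diag(3),
               ignore_attr = TRUE)
  expect_equal(unname(build_contingency(c(1, 1, 1), c(1, 2, 2))),
               matrix(c(1, 2), 1), ignore_attr = TRUE)
  # margins are the cluster sizes, entries sum to n
  set.seed(5)
  pw <- random_partition(40, 4); pc <- random_partition(40, 6)
  a <- build_contingency(pw, pc)
  expect_equal(sum(a), 40)
  expect_equal(unname(rowSums(a)), unname(tabulate(pw)))
  expect_equal(unname(colSums(a)), unname(tabulate(pc)))
  expect_error(build_contingency(c(1, 2), c(1, 2, 2)),
               class = "crossclust_input_error")
  expect_error(build_contingency(c(1, 3), c(1, 2)),  # label 2 missing
               class = "crossclust_input_error")
})

test_that("max_trace_overlap solves the stated examples", {
  asg <- max_trace_overlap(diag(c(4, 5)))
  expect_equal(asg$mo, 9L)
  expect_equal(asg$col_for_row, c(1L, 2L))

  asg <- max_trace_overlap(rbind(c(3, 0, 1), c(0, 2, 0)))
  expect_equal(asg$mo, 5L)
  expect_equal(asg$col_for_row, c(1L, 2L))

  expect_equal(max_trace_overlap(matrix(2, 2, 2))$mo, 4L)  # tie, either map
  expect_error(max_trace_overlap(rbind(c(1, -1), c(0, 2))),
               class = "crossclust_input_error")
})

test_that("assignment solve equals exhaustive injective search", {
  set.seed(2024)
  for (rep in 1:300) {
    r <- sample(1:5, 1); s <- sample(r:6, 1)
    if (runif(1) < 0.15) { tmp <- r; r <- s; s <- tmp }  # some r > s shapes
    a <- matrix(sample(0:9, r * s, replace = TRUE), r, s)
    asg <- max_trace_overlap(a)
    expect_identical(asg$mo, as.integer(brute_mo(a)))
    # reported mapping realizes mo and is injective
    m <- !is.na(asg$col_for_row)
    expect_equal(sum(a[cbind(which(m), asg$col_for_row[m])]), asg$mo)
    expect_false(anyDuplicated(asg$col_for_row[m]) > 0)
  }
})

test_that("overlap respects the nonempty-column bound", {
  set.seed(77)
  for (rep in 1:50) {
    n <- 30
    r <- sample(2:4, 1); s <- sample((r + 1):6, 1)
    pw <- random_partition(n, r); pc <- random_partition(n, s)
    mo <- max_trace_overlap(build_contingency(pw, pc))$mo
    expect_lte(mo, n - (s - r))
    expect_gte(mo, 0)
  }
})

test_that("consensus keeps agreeing items and flags the rest as outliers", {
  pw <- c(1, 1, 2, 2, 2); pc <- c(1, 1, 2, 2, 3)
  asg <- max_trace_overlap(build_contingency(pw, pc))
  expect_equal(unname(consensus_partition(pw, pc, asg)), c(1, 1, 2, 2, 0))

  p <- c(1, 2, 2, 3, 3)
  asg <- max_trace_overlap(build_contingency(p, p))
  expect_equal(unname(consensus_partition(p, p, asg)), p)  # no outliers

  # label-permutation invariance of the consensus
  pw <- c(1, 1, 2, 2); pc <- c(2, 2, 1, 1)
  asg <- max_trace_overlap(build_contingency(pw, pc))
  expect_equal(unname(consensus_partition(pw, pc, asg)), c(1, 1, 2, 2))
})

test_that("relabeling either parent leaves the overlap unchanged", {
  # mo (and hence every selection decision and the outlier count) is
  # invariant under relabeling; the particular optimal mapping need not be
  # unique on tied tables, so only tie-free structure pins the partition.
  set.seed(9)
  for (rep in 1:20) {
    n <- 30
    pw <- random_partition(n, 3); pc <- random_partition(n, 5)
    base_asg <- max_trace_overlap(build_contingency(pw, pc))
    pw2 <- match(pw, sample(3))
    pc2 <- match(pc, sample(5))
    asg2 <- max_trace_overlap(build_contingency(pw2, pc2))
    expect_identical(asg2$mo, base_asg$mo)
  }
  # unique optimum: the induced partial partition is stable up to names
  pw <- rep(c(1, 2, 3), times = c(10, 10, 5))
  pc <- c(rep(1, 10), rep(2, 9), 3, rep(4, 5))
  base <- consensus_partition(pw, pc,
                              max_trace_overlap(build_contingency(pw, pc)))
  for (rep in 1:10) {
    pw2 <- match(pw, sample(3)); pc2 <- match(pc, sample(4))
    cons2 <- consensus_partition(pw2, pc2,
                                 max_trace_overlap(build_contingency(pw2, pc2)))
    expect_equal(cons2 == 0, base == 0)
    expect_equal(adjusted_rand(base + 1L, cons2 + 1L), 1)
  }
})

test_that("non-outlier count always equals the overlap at the optimum", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 0, 0.5), 30), matrix(rnorm(60, 8, 0.5), 30))
  res <- cross_cluster(x, kw_min = 2, kw_max = 4, kc_max = 8)
  expect_equal(sum(res$labels > 0), res$mo)
  expect_equal(res$mo_matrix[as.character(res$n_w_star),
                             as.character(res$n_c_star)], res$mo)
  expect_equal(max(res$mo_matrix, na.rm = TRUE), res$mo)
})

test_that("two tight clouds plus a remote point: the point is the outlier", {
  # the remote point must be near enough that Ward absorbs it into a cloud
  # at k = 2 (else it is already its own Ward cluster), yet far enough that
  # complete linkage isolates it as a singleton at k = 3
  set.seed(12)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10),
             matrix(rnorm(20, 10, 0.1), 10),
             c(30, 30))
  rownames(x) <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10), "remote")
  res <- cross_cluster(x, kw_min = 2, kw_max = 4, kc_max = 6)
  expect_equal(res$n_w_star, 2L)
  expect_equal(res$k, 2L)
  expect_identical(res$outlier_ids, "remote")
  expect_setequal(unique(res$labels[1:10]), 1L)
  expect_setequal(unique(res$labels[11:20]), 2L)
})

test_that("five identical-coordinate groups recover all five clusters", {
  x <- do.call(rbind, lapply(0:4, function(g)
    matrix(rep(c(g * 10, g * 10), each = 8), 8, 2)))
  res <- cross_cluster(x, kw_min = 2, kw_max = 7, kc_max = 10)
  expect_equal(res$k, 5L)
  # a finer CL cut always has n_C > n_W nonempty clusters, so at least
  # n_C - n_W items sit off the matched diagonal: mo = n - 1 at best
  expect_equal(res$mo, nrow(x) - 1L)
  expect_equal(length(res$outlier_ids), 1L)
  truth <- rep(1:5, each = 8)
  keep <- res$labels > 0
  expect_equal(adjusted_rand(res$labels[keep], truth[keep]), 1)
})

test_that("the scan is deterministic", {
  set.seed(8)
  x <- matrix(rnorm(200), 50)
  r1 <- cross_cluster(x, kw_min = 2, kw_max = 6, kc_max = 10)
  r2 <- cross_cluster(x, kw_min = 2, kw_max = 6, kc_max = 10)
  expect_identical(r1, r2)
})

test_that("scan bounds are validated with the violated bound named", {
  x <- matrix(rnorm(60), 20)
  expect_error(cross_cluster(x, kw_min = 1), "kw_min",
               class = "crossclust_config_error")
  expect_error(cross_cluster(x, kw_min = 5, kw_max = 3), "kw_max",
               class = "crossclust_config_error")
  expect_error(cross_cluster(x, kw_max = 10, kc_max = 10), "kc_max",
               class = "crossclust_config_error")
  expect_error(cross_cluster(x, kw_max = 18, kc_max = 20), "kc_max",
               class = "crossclust_config_error")  # kc_max > n - 1
  expect_error(cross_cluster(), class = "crossclust_input_error")
})

test_that("mo_matrix covers exactly the n_C > n_W pairs", {
  set.seed(14)
  x <- matrix(rnorm(100), 25)
  res <- cross_cluster(x, kw_min = 2, kw_max = 5, kc_max = 7)
  for (i in rownames(res$mo_matrix)) for (j in colnames(res$mo_matrix)) {
    if (as.integer(j) > as.integer(i)) {
      expect_false(is.na(res$mo_matrix[i, j]))
      expect_lte(res$mo_matrix[i, j], 25)
    } else {
      expect_true(is.na(res$mo_matrix[i, j]))
    }
  }
})

test_that("five-behaviour data: signal classes map to distinct clusters", {
  # scaled-down design, low noise, outliers included
  hits <- 0L
  for (s in 1:5) {
    ds <- simulate_dataset(small_design(), seed = 400 + s)
    res <- cross_cluster(ds$matrix)
    conf <- majority_confusion(res$labels, ds$truth)
    reps <- conf$representative[conf$class %in% 1:5]
    ari <- adjusted_rand(res$labels, ds$truth)
    if (anyDuplicated(reps) == 0 && ari > 0.85) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("precomputed distances and raw matrices give identical results", {
  set.seed(19)
  x <- matrix(rnorm(120), 30)
  rownames(x) <- paste0("item_", 1:30)
  r1 <- cross_cluster(x, kw_min = 2, kw_max = 4, kc_max = 8)
  r2 <- cross_cluster(d = pairwise_distances(x), kw_min = 2, kw_max = 4,
                      kc_max = 8)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$mo_matrix, r2$mo_matrix)
})
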