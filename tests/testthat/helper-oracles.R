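# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity from first principles.

# Maximum diagonal sum over all injective row -> column matchings,
# by exhaustive recursion (feasible for r <= 5, s <= 6).
brute_mo <- function(a) {
  if (nrow(a) > ncol(a)) a <- t(a)
  r <- nrow(a); s <- ncol(a)
  rec <- function(row, used) {
    if (row > r) return(0)
    best <- -Inf
    for (col in setdiff(seq_len(s), used)) {
      best <- max(best, a[row, col] + rec(row + 1L, c(used, col)))
    }
    best
  }
  rec(1L, integer())
}

# Pair-counting adjusted Rand index over all item pairs.
brute_ari <- function(p1, p2) {
  n <- length(p1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) n11 <- n11 + 1
    else if (!s1 && !s2) n00 <- n00 + 1
    else if (s1) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}

# Agglomeration by direct Lance-Williams recursion on the distance matrix.
# complete: D(ij,k) = max(D(i,k), D(j,k)).
# ward (distance-scale variant): D(ij,k)^2 =
#   ((ni+nk) D(i,k)^2 + (nj+nk) D(j,k)^2 - nk D(i,j)^2) / (ni+nj+nk).
brute_linkage_heights <- function(d, method) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      v <- dm[active[ii], active[jj]]
      if (v < best) { best <- v; bi <- active[ii]; bj <- active[jj] }
    }
    heights <- c(heights, best)
    others <- setdiff(active, c(bi, bj))
    for (k in others) {
      dm[bi, k] <- dm[k, bi] <- if (method == "complete") {
        max(dm[bi, k], dm[bj, k])
      } else {
        sqrt(((sizes[bi] + sizes[k]) * dm[bi, k]^2 +
              (sizes[bj] + sizes[k]) * dm[bj, k]^2 -
              sizes[k] * best^2) / (sizes[bi] + sizes[bj] + sizes[k]))
      }
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    active <- setdiff(active, bj)
  }
  heights
}

# Greedy Ward agglomeration straight from the coordinates: at every step
# merge the pair of groups whose union least increases the within-group
# sum of squared errors; report heights sqrt(2 * increase), the
# distance-scale convention.
brute_ward_sse_heights <- function(x) {
  groups <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
      gi <- groups[[i]]; gj <- groups[[j]]
      ci <- colMeans(x[gi, , drop = FALSE])
      cj <- colMeans(x[gj, , drop = FALSE])
      dsse <- length(gi) * length(gj) / (length(gi) + length(gj)) *
        sum((ci - cj)^2)
      if (dsse < best) { best <- dsse; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(2 * best))
    groups[[bj]] <- c(groups[[bj]], groups[[bi]])
    groups[[bi]] <- NULL
  }
  heights
}

# Leaf sets under each internal merge of an hclust tree.
merge_members <- function(tree) {
  m <- tree$merge
  out <- vector("list", nrow(m))
  grab <- function(v) if (v < 0) -v else out[[v]]
  for (i in seq_len(nrow(m))) out[[i]] <- c(grab(m[i, 1]), grab(m[i, 2]))
  out
}

# Silhouette widths by direct double loop.
brute_silhouette <- function(d, p) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  vapply(seq_len(n), function(i) {
    own <- which(p == p[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(p), p[i]),
                    function(g) mean(dm[i, p == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Shannon entropy in bits, via table().
entropy_bits_ref <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# Uniform random partition guaranteed to use every label 1..k.
random_partition <- function(n, k) {
  repeat {
    p <- sample.int(k, n, replace = TRUE)
    if (length(unique(p)) == k) return(p)
  }
}

# Scaled-down variant of the five-behaviour design for fast unit tests.
small_design <- function(sigma = 0.2, n_outliers = 15L) {
  sim_config(class_counts = c(constant = 50L, increasing = 25L,
                              decreasing = 70L, oscillating = 30L,
                              convex = 10L),
             sigma = sigma, n_outliers = n_outliers)
}
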