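# Seeded generator of synthetic expression profiles: five deterministic
# behaviours over the samples, Gaussian noise, and uniform outlier profiles
# bounded by the maximum simulated value - the benchmark design every other
# module is tested against.

BEHAVIOR_CLASSES <- c("constant", "increasing", "decreasing",
                      "oscillating", "convex")

#' Noise-free behaviour template
#'
#' The five expression behaviours over the samples: `constant` at a
#' positive value (the amplitude), `increasing` (linear ramp 0 to
#' amplitude), `decreasing` (ramp amplitude to 0), `oscillating`
#' (alternating amplitude and 0), and `convex` (symmetric parabola with
#' minimum 0 at the middle sample and endpoints at the amplitude).
#'
#' @param class One of `"constant"`, `"increasing"`, `"decreasing"`,
#'   `"oscillating"`, `"convex"`.
#' @param n_samples Number of samples (>= 2; >= 3 for `convex`).
#' @param amplitude Positive scale of all templates (default 4).
#' @return Numeric vector of length `n_samples`.
#' @examples
#' behavior_template("increasing", 5, 4)   # 0 1 2 3 4
#' @export
behavior_template <- function(class, n_samples = 5L, amplitude = 4) {
  if (!is.character(class) || length(class) != 1L ||
      !class %in% BEHAVIOR_CLASSES)
    stop_config("unknown behavior class '%s'; use one of: %s",
                as.character(class)[1L], paste(BEHAVIOR_CLASSES, collapse = ", "))
  if (n_samples < 2L) stop_config("n_samples must be >= 2")
  if (class == "convex" && n_samples < 3L)
    stop_config("the convex template needs n_samples >= 3")
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop_config("amplitude must be positive")
  switch(class,
    constant    = rep(amplitude, n_samples),
    increasing  = seq(0, amplitude, length.out = n_samples),
    decreasing  = seq(amplitude, 0, length.out = n_samples),
    oscillating = amplitude * (seq_len(n_samples) %% 2L),
    convex      = {
      x <- seq(-1, 1, length.out = n_samples)
      amplitude * x^2
    })
}

#' Simulation configuration
#'
#' Parameters of the synthetic-profile design: five behaviour classes over
#' `n_samples` samples with class sizes `class_counts`, i.i.d. Gaussian
#' noise with standard deviation `sigma` on every signal entry, and
#' `n_outliers` profiles drawn coordinate-wise from Uniform(0, M), where M
#' is the maximum entry of the signal block (`outlier_bound` chooses
#' whether M is taken after noise is added, the default, or before).
#'
#' The default class sizes (500, 250, 700, 300, 100; total 1850) and noise
#' levels follow the benchmark design this package reproduces.  `total`
#' rescales the class sizes proportionally to another overall signal-row
#' count (largest class absorbs rounding).
#'
#' @param n_samples Number of samples (default 5).
#' @param class_counts Named integer vector of profiles per behaviour.
#' @param sigma Positive noise standard deviation (default 0.2).
#' @param n_outliers Number of uniform outlier profiles (default 150).
#' @param amplitude Shared template amplitude (default 4).
#' @param outlier_bound `"post_noise"` (default) or `"pre_noise"`.
#' @param total Optional target total signal-row count.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 5L,
                       class_counts = c(constant = 500L, increasing = 250L,
                                        decreasing = 700L, oscillating = 300L,
                                        convex = 100L),
                       sigma = 0.2, n_outliers = 150L, amplitude = 4,
                       outlier_bound = c("post_noise", "pre_noise"),
                       total = NULL) {
  outlier_bound <- match.arg(outlier_bound)
  if (n_samples < 2L) stop_config("n_samples must be >= 2")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_config("sigma must be a single positive number")
  if (is.null(names(class_counts)) ||
      !setequal(names(class_counts), BEHAVIOR_CLASSES))
    stop_config("class_counts must be named with: %s",
                paste(BEHAVIOR_CLASSES, collapse = ", "))
  class_counts <- class_counts[BEHAVIOR_CLASSES]
  if (any(class_counts < 0) || !is_whole(class_counts))
    stop_config("class_counts must be nonnegative integers")
  if (!is.null(total)) {
    scaled <- round(class_counts / sum(class_counts) * total)
    scaled[which.max(scaled)] <- scaled[which.max(scaled)] + total - sum(scaled)
    class_counts <- scaled
  }
  if (n_outliers < 0 || !is_whole(n_outliers))
    stop_config("n_outliers must be a nonnegative integer")
  structure(list(n_samples = as.integer(n_samples),
                 class_counts = as.integer(class_counts) |>
                   stats::setNames(BEHAVIOR_CLASSES),
                 sigma = sigma, n_outliers = as.integer(n_outliers),
                 amplitude = amplitude, outlier_bound = outlier_bound),
            class = "sim_config")
}

#' Generate a synthetic profile dataset
#'
#' Draws the dataset described by a [sim_config()]: each signal row is its
#' class template plus i.i.d. Gaussian noise, and outlier rows are drawn
#' coordinate-wise from Uniform(0, M) with M the maximum of the signal
#' block.  Fully reproducible for a given `(config, seed)` pair; the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed.
#' @return A list of class `"sim_dataset"` with `matrix` (rows
#'   `gene_0001`, ... in class order, outliers last), `truth` (integer
#'   labels 1..5 in the order constant, increasing, decreasing,
#'   oscillating, convex; 0 for outlier rows), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config"))
    stop_input("'config' must come from sim_config()")
  with_seed(seed, {
    counts <- config$class_counts
    templates <- vapply(BEHAVIOR_CLASSES, behavior_template,
                        numeric(config$n_samples),
                        n_samples = config$n_samples,
                        amplitude = config$amplitude)  # n_samples x 5
    signal_mean <- templates[, rep(seq_along(counts), counts), drop = FALSE]
    signal <- t(signal_mean)
    noise <- matrix(rnorm(length(signal), sd = config$sigma),
                    nrow = nrow(signal))
    noised <- signal + noise
    m <- if (config$outlier_bound == "post_noise") max(noised) else max(signal)
    outliers <- matrix(runif(config$n_outliers * config$n_samples, 0, m),
                       nrow = config$n_outliers, ncol = config$n_samples)
    x <- rbind(noised, outliers)
    rownames(x) <- sprintf("gene_%04d", seq_len(nrow(x)))
    colnames(x) <- sprintf("sample_%d", seq_len(config$n_samples))
    truth <- c(rep(seq_along(counts), counts), rep(0L, config$n_outliers))
    structure(list(matrix = x, truth = as.integer(truth), config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated profile dataset: %d signal + %d outlier rows, %d samples (sigma = %g)\n",
              sum(x$config$class_counts), x$config$n_outliers,
              x$config$n_samples, x$config$sigma))
  invisible(x)
}

#' Replicated simulation study
#'
#' For every configuration in `cfg_grid` and every replicate, generates a
#' dataset, runs [cross_cluster()] and scores the result against the truth
#' (outliers treated as a single class): adjusted Rand index, information
#' gain, recovered cluster count, and the per-class majority-mapping
#' confusion measures.  Optionally also scores plain Ward and complete
#' linkage cut at their ASW-selected k, the usual baselines.
#'
#' @param cfg_grid A [sim_config()] or list of them.
#' @param n_reps Replicates per configuration (>= 1).
#' @param seed Base seed; replicate `r` of configuration `g` uses seed
#'   `seed + 1000 * g + r`, recorded in the output.
#' @param kw_min,kw_max,kc_max Scan parameters passed to [cross_cluster()].
#' @param baselines Also compute `ari_ward` / `ari_cl` at ASW-selected k
#'   over `2..kc_max` (default `FALSE`).
#' @return A [tibble::tibble] with one row per configuration x replicate x
#'   truth class; replicate-level columns (`sigma`, `seed`, `k_recovered`,
#'   `n_w_star`, `n_c_star`, `n_outliers_found`, `ari`,
#'   `information_gain`, and baselines when requested) are repeated across
#'   the class rows (`class`, `sensitivity`, `specificity`, `ppv`,
#'   `acc_g`, `auc`).
#' @export
run_study <- function(cfg_grid, n_reps = 1L, seed = 1L,
                      kw_min = 2L, kw_max = 19L, kc_max = 20L,
                      baselines = FALSE) {
  if (inherits(cfg_grid, "sim_config")) cfg_grid <- list(cfg_grid)
  if (!is.list(cfg_grid) ||
      !all(vapply(cfg_grid, inherits, TRUE, "sim_config")))
    stop_input("'cfg_grid' must be a sim_config or a list of them")
  if (n_reps < 1L && length(cfg_grid) > 0L)
    stop_input("n_reps must be >= 1")
  rows <- list()
  for (g in seq_along(cfg_grid)) {
    cfg <- cfg_grid[[g]]
    for (r in seq_len(n_reps)) {
      rep_seed <- as.integer(seed + 1000L * g + r)
      row <- tryCatch(
        study_one(cfg, rep_seed, kw_min, kw_max, kc_max, baselines),
        error = function(e) stop_internal(
          "replicate failed (config %d, replicate %d): %s",
          g, r, conditionMessage(e)))
      row$config <- g
      row$replicate <- r
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(config = integer(), replicate = integer(),
                          sigma = numeric(), seed = integer(),
                          class = integer(), k_recovered = integer(),
                          n_w_star = integer(), n_c_star = integer(),
                          n_outliers_found = integer(), ari = numeric(),
                          information_gain = numeric(),
                          sensitivity = numeric(), specificity = numeric(),
                          ppv = numeric(), acc_g = numeric(), auc = numeric()))
  }
  out <- do.call(rbind, rows)
  tibble::as_tibble(out[, c("config", "replicate", "sigma", "seed", "class",
                            "k_recovered", "n_w_star", "n_c_star",
                            "n_outliers_found", "ari", "information_gain",
                            "sensitivity", "specificity", "ppv", "acc_g",
                            "auc",
                            intersect(c("ari_ward", "ari_cl", "k_ward", "k_cl"),
                                      colnames(out)))])
}

study_one <- function(cfg, rep_seed, kw_min, kw_max, kc_max, baselines) {
  ds <- simulate_dataset(cfg, seed = rep_seed)
  res <- cross_cluster(ds$matrix, kw_min = kw_min, kw_max = kw_max,
                       kc_max = kc_max)
  conf <- majority_confusion(res$labels, ds$truth)
  out <- data.frame(
    sigma = cfg$sigma, seed = rep_seed, class = conf$class,
    k_recovered = res$k, n_w_star = res$n_w_star, n_c_star = res$n_c_star,
    n_outliers_found = length(res$outlier_ids),
    ari = adjusted_rand(res$labels, ds$truth, outliers_as_cluster = TRUE),
    information_gain = information_gain(res$labels, ds$truth),
    sensitivity = conf$sensitivity, specificity = conf$specificity,
    ppv = conf$ppv, acc_g = conf$acc_g, auc = conf$auc)
  if (baselines) {
    d <- pairwise_distances(ds$matrix)
    krange <- 2:min(kc_max, attr(d, "Size") - 1L)
    for (meth in c("ward", "cl")) {
      tree <- linkage(d, if (meth == "ward") "ward" else "complete")
      sel <- select_k_by_asw(d, tree, krange)
      labs <- cut_tree(tree, sel$k_best)
      out[[paste0("ari_", meth)]] <-
        adjusted_rand(labs, ds$truth, outliers_as_cluster = TRUE)
      out[[paste0("k_", meth)]] <- sel$k_best
    }
  }
  out
}
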