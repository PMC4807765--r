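# crossclust

Partial clustering with automatic estimation of the number of clusters,
for gene-expression profiles and other numeric feature matrices.

## The problem and the method

Routine clustering of expression data runs into two chronic problems:
the number of clusters `K` must be guessed in advance, and every gene or
sample is forced into some cluster even when it is noise.  Cross-clustering
solves both by combining two classic agglomerative hierarchies built from
the same distance matrix: **Ward's minimum variance**, which forms compact
well-separated clusters and is a reliable judge of `K`, and **complete
linkage**, which pushes outliers into small and singleton clusters.

For every Ward cut into `n_W` clusters crossed with a finer
complete-linkage cut into `n_C > n_W` clusters, the two partitions are
cross-tabulated into a contingency table *A* (entry *a<sub>rs</sub>* =
items in Ward cluster *r* and complete-linkage cluster *s*).  The columns
of *A* are permuted to maximise the diagonal sum — the **maximum overlap**

> MO(n_W, n_C) = max over injective π of Σ<sub>r</sub> a<sub>r,π(r)</sub>

solved exactly as a linear assignment problem.  The pair (n_W\*, n_C\*)
with the largest MO fixes the number of clusters (the Ward count) and the
consensus memberships; items the two hierarchies disagree on — including
the members of the `n_C − n_W` unmatched complete-linkage clusters — are
left unassigned as outliers (label `0`).  The procedure is deterministic:
no initialisation, no randomness, identical results on every run.

The package also ships the evaluation indices used to benchmark such
clusterings (adjusted Rand index with an outliers-as-one-cluster
convention, majority-mapping sensitivity/specificity/PPV/geometric
accuracy/AUC, information gain, silhouette widths and average-silhouette
selection of `k`) and a seeded generator of the five-behaviour synthetic
benchmark (constant/increasing/decreasing/oscillating/convex templates
plus Gaussian noise plus uniform outlier profiles).

## Worked example

```r
library(crossclust)

ds  <- simulate_dataset(sim_config(sigma = 0.2), seed = 1)  # 2000 x 5
res <- cross_cluster(ds$matrix)    # defaults: kw 2..19, kc_max 20
res
#> Cross-clustering result
#>   items: 2000   selected pair: n_W = 19, n_C = 20 (MO = 1956)
#>   consensus clusters: 18   outliers: 44

adjusted_rand(res$labels, ds$truth)          # outliers as one cluster
#> [1] 0.981
information_gain(res$labels, ds$truth)
#> [1] 2.262
majority_confusion(res$labels, ds$truth)[2:6, c("class", "sensitivity", "ppv", "auc")]
#>   class sensitivity   ppv   auc
#> 2     1           1 0.996 0.999
#> 3     2           1 0.988 0.999
#> 4     3           1 0.999 1.000
#> 5     4           1 0.993 0.999
#> 6     5           1 0.952 0.999
```

On this contaminated dataset the consensus recovers every signal class
with sensitivity 1 (each class maps to its own consensus cluster by
majority), flags 44 profiles as outliers, and scores ARI 0.98 against the
ground truth with the 150 injected uniform profiles treated as one extra
class.  The extra consensus clusters beyond the five signal classes are
clumps of injected outliers; see the vignette
(`vignettes/cross-clustering.Rmd`) for why contamination pushes the
selected pair to fine cuts, and for the method's behaviour on clean data.

## Command line

```sh
crossclust simulate --out-prefix sim --sigma 0.2 --seed 1
crossclust cc --input sim.matrix.tsv --out-prefix run --kc-max 20
crossclust evaluate --pred run.labels.tsv --truth sim.truth.tsv
crossclust study --out study.tsv --sigmas 0.2,1.5 --reps 3 --seed 1
```

`cc` writes `run.labels.tsv` (item, label; `0` = outlier) and
`run.summary.json` (selected pair, full MO matrix, parameters, version).
Exit codes: 0 success, 1 input error, 2 internal error.

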