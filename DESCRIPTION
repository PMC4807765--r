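Package: crossclust
Title: Cross-Clustering: Partial Clustering with Automatic Estimation of
    the Number of Clusters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partial clustering of expression profiles (or any numeric
    feature matrix) by combining Ward's minimum-variance and
    complete-linkage hierarchical clusterings.  Dendrogram cuts from the
    two methods are cross-tabulated and the column permutation maximising
    the diagonal of the contingency table (solved exactly as a linear
    assignment problem) measures their consensus; scanning cluster-count
    pairs and keeping the maximum-overlap pair estimates the number of
    clusters and leaves poorly supported items unassigned as outliers.
    Includes the evaluation indices used to benchmark such clusterings
    (adjusted Rand index with an outliers-as-one-cluster convention,
    majority-mapping confusion measures, information gain, silhouette
    widths and average-silhouette-width model selection), a seeded
    generator of five-behaviour synthetic expression profiles with
    uniform outlier contamination, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
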