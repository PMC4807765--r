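# Delimited-text ingestion and result serialisation.

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_input("'%s' is empty", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read an items-by-features matrix from delimited text
#'
#' Expects a header row and item identifiers in the first column.  The
#' delimiter (tab or comma) is auto-detected from the header unless
#' forced.  Missing or non-numeric cells and duplicate identifiers are
#' rejected with the offending location named; no silent imputation.
#'
#' @param path File path.
#' @param delimiter Optional delimiter (`"\t"` or `","`); auto-detected
#'   when `NULL`.
#' @param transpose Cluster the columns instead of the rows (the file is
#'   transposed after reading).
#' @return Numeric matrix with unique row names.
#' @export
read_matrix <- function(path, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  sep <- if (is.null(delimiter)) detect_delimiter(path) else delimiter
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", quote = "\""),
    error = function(e) stop_input("cannot parse '%s': %s", path,
                                   conditionMessage(e)))
  if (ncol(raw) < 2L)
    stop_input("'%s' must have an identifier column plus >= 1 numeric column",
               path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    dup_rows <- which(duplicated(ids) | duplicated(ids, fromLast = TRUE))
    stop_input("duplicate item identifiers in '%s' (data rows %s)", path,
               paste(utils::head(dup_rows, 10L), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop_input("missing or non-numeric value at data row %d ('%s'), column '%s'",
               b[1L], ids[b[1L]], colnames(raw)[-1L][b[2L]])
  }
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  if (transpose) num <- t(num)
  validate_expression_matrix(num, min_items = 2L)
}

#' Apply log2 transform and per-row standardization
#'
#' Optional preprocessing applied in the fixed order log2 first, then
#' per-row scaling to mean 0 and variance 1 (the usual handling of raw
#' intensity data before clustering).  `log2` of nonpositive values is an
#' error: add an offset to the data explicitly rather than relying on a
#' hidden pseudo-count.
#'
#' @param x Numeric matrix.
#' @param log2 Apply `log2` to all entries.
#' @param standardize Scale each row to mean 0, variance 1.
#' @return The transformed matrix.
#' @export
preprocess_matrix <- function(x, log2 = FALSE, standardize = FALSE) {
  x <- validate_expression_matrix(x, min_items = 2L)
  if (log2) {
    if (any(x <= 0))
      stop_input(paste0("log2 transform requires strictly positive values; ",
                        "add an explicit offset to your data first ",
                        "(first offending row: '%s')"),
                 rownames(x)[which(apply(x, 1L, min) <= 0)[1L]])
    x <- base::log2(x)
  }
  if (standardize) x <- standardize_rows(x)
  x
}

#' Write a cross-clustering result to disk
#'
#' Writes `<prefix>.labels.tsv` (columns `item_id`, `label`; 0 marks
#' outliers) and `<prefix>.summary.json` (selected pair, cluster count,
#' MO matrix, outlier count, parameters, package version).  Re-reading
#' the labels file with [read_labels()] reproduces the partition exactly.
#'
#' @param res A `"cc_result"` from [cross_cluster()].
#' @param out_prefix Path prefix for the two output files.
#' @param extra Optional named list merged into the JSON summary (the CLI
#'   stores its full flag set here).
#' @return Character vector of the two paths, invisibly.
#' @export
write_result <- function(res, out_prefix, extra = NULL) {
  if (!inherits(res, "cc_result"))
    stop_input("'res' must be a cc_result from cross_cluster()")
  labels_path <- paste0(out_prefix, ".labels.tsv")
  json_path <- paste0(out_prefix, ".summary.json")
  tab <- data.frame(item_id = names(res$labels), label = unname(res$labels))
  tryCatch({
    utils::write.table(tab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summary <- c(list(
      tool = "crossclust",
      version = as.character(utils::packageVersion("crossclust")),
      n_items = res$n_items,
      n_w_star = res$n_w_star, n_c_star = res$n_c_star, mo = res$mo,
      k = res$k, n_outliers = length(res$outlier_ids),
      single_cluster_advisory = res$single_cluster_advisory,
      params = res$params,
      mo_matrix = list(n_w = as.integer(rownames(res$mo_matrix)),
                       n_c = as.integer(colnames(res$mo_matrix)),
                       mo = res$mo_matrix)), extra)
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }, error = function(e) stop_input("cannot write results to '%s*': %s",
                                    out_prefix, conditionMessage(e)))
  invisible(c(labels = labels_path, summary = json_path))
}

#' Read a label table written by [write_result()] or the CLI
#'
#' @param path TSV with columns `item_id` and `label`.
#' @return Named integer label vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_input("label file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("item_id", "label") %in% colnames(tab)))
    stop_input("'%s' must have columns 'item_id' and 'label'", path)
  labs <- suppressWarnings(as.integer(tab$label))
  if (anyNA(labs))
    stop_input("non-integer label at data row %d of '%s'",
               which(is.na(labs))[1L], path)
  stats::setNames(labs, tab$item_id)
}
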