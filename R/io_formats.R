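# On-disk formats: expression TSV (series-matrix-like "!" comments skipped),
# outcome TSV, weighted graphs (GraphML / edge list), feature matrices,
# result tables.  All writers emit "."-decimal, LF-terminated text.

MISSING_TOKENS <- c("", "na", "nan", "null")

#' Construct an expression matrix object
#'
#' A thin container for a features-by-samples real matrix with unique
#' feature and sample identifiers and a platform tag.  Expression data are
#' stored in the features x samples orientation (the convention of GEO
#' series matrices); pipeline stages transpose internally when they need
#' samples x features.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids character vectors; taken from `dimnames`
#'   when `NULL`.
#' @param platform_tag free-text provenance tag (e.g. cohort or platform).
#' @param n_dropped number of features dropped during loading (missing
#'   values), recorded for the load report.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL,
                              platform_tag = "unknown", n_dropped = 0L) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (ncol(values) < 2) stop("need at least 2 samples")
  if (nrow(values) < 1) stop("need at least 1 feature")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids,
         platform_tag = platform_tag, n_dropped = as.integer(n_dropped)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (platform '%s'",
              nrow(x$values), ncol(x$values), x$platform_tag))
  if (x$n_dropped > 0) cat(sprintf(", %d features dropped at load", x$n_dropped))
  cat(")\n")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' First column holds feature ids, first row sample ids.  Header or comment
#' lines starting with `!` (series-matrix dialect) are skipped.  Recognised
#' missing-value tokens are the empty field, `NA`, `NaN` and `null`
#' (case-insensitive); features (rows) containing any missing value are
#' dropped when `drop_missing` is set, and the count of dropped rows is
#' recorded on the returned object.
#'
#' @param path file path.
#' @param drop_missing drop features with any missing cell (default `TRUE`).
#'   When `FALSE`, any missing value is an error.
#' @param platform_tag provenance tag stored on the result.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, drop_missing = TRUE,
                                   platform_tag = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- cells[-1]
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  n <- length(sample_ids)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n,
                 dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    # a trailing empty field is swallowed by strsplit; restore it
    if (length(row) == n) row <- c(row, "")
    if (length(row) != n + 1L)
      stop(sprintf("row '%s' has %d fields, expected %d",
                   feature_ids[i], length(row) - 1L, n))
    cell <- row[-1]
    is_missing <- tolower(trimws(cell)) %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is_missing)
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   cell[bad[1]], feature_ids[i], sample_ids[bad[1]]))
    vals[i, ] <- num
  }
  has_na <- rowSums(is.na(vals)) > 0
  if (any(has_na) && !drop_missing)
    stop(sum(has_na), " features contain missing values (drop_missing = FALSE)")
  expression_matrix(vals[!has_na, , drop = FALSE], platform_tag = platform_tag,
                    n_dropped = sum(has_na))
}

#' Write an expression matrix as TSV
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(paste(c("feature_id", x$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x$values)), function(i)
    paste(c(x$feature_ids[i], format_num(x$values[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

# full-precision, integer-exact textual rendering of doubles
format_num <- function(v) {
  out <- sprintf("%.17g", v)
  whole <- v == round(v) & abs(v) < 2^53
  out[whole] <- sprintf("%.0f", v[whole])
  out
}

#' Construct an outcome table
#'
#' @param sample_ids character vector of sample identifiers.
#' @param outcomes named list (or data.frame) of binary 0/1 vectors, one per
#'   clinical outcome (e.g. "Death from disease").
#' @return an object of class `outcome_table`.
#' @export
outcome_table <- function(sample_ids, outcomes) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in outcome table")
  outcomes <- lapply(outcomes, function(v) {
    v <- as.integer(v)
    if (length(v) != length(sample_ids) || anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("outcomes must be complete binary 0/1 vectors, one value per sample")
    v
  })
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("every outcome needs a name")
  structure(list(sample_ids = sample_ids, outcomes = outcomes),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  prev <- vapply(x$outcomes, mean, numeric(1))
  cat(sprintf("outcome_table: %d samples; %s\n", length(x$sample_ids),
              paste(sprintf("'%s' (prevalence %.3f)", names(prev), prev),
                    collapse = ", ")))
  invisible(x)
}

#' Fetch one outcome as a named binary vector
#' @param x an [outcome_table()].
#' @param name outcome name.
#' @export
outcome_vector <- function(x, name) {
  stopifnot(inherits(x, "outcome_table"))
  if (!name %in% names(x$outcomes))
    stop("unknown outcome '", name, "'; available: ",
         paste(names(x$outcomes), collapse = ", "))
  setNames(x$outcomes[[name]], x$sample_ids)
}

#' Read a clinical outcome TSV
#'
#' The file must have a sample-id column (first column) and one column per
#' outcome with values in {0, 1}.  Unrequested columns are ignored.
#'
#' @param path file path.
#' @param outcome_names outcomes to load; default all columns.
#' @param expected_ids optional sample ids that must all be present
#'   (e.g. the samples of the matching expression matrix).
#' @return an [outcome_table()] restricted to `outcome_names`, file order
#'   preserved.
#' @export
read_outcomes <- function(path, outcome_names = NULL, expected_ids = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  avail <- colnames(df)[-1]
  if (is.null(outcome_names)) outcome_names <- avail
  missing_col <- setdiff(outcome_names, avail)
  if (length(missing_col))
    stop("unknown outcome(s) ", paste(missing_col, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  if (!is.null(expected_ids)) {
    absent <- setdiff(expected_ids, ids)
    if (length(absent))
      stop("samples missing from outcome table: ",
           paste(absent, collapse = ", "))
  }
  out <- lapply(outcome_names, function(nm) {
    v <- df[[nm]]
    if (!all(v %in% c("0", "1")))
      stop("outcome '", nm, "' has non-binary values: ",
           paste(unique(setdiff(v, c("0", "1"))), collapse = ", "))
    as.integer(v)
  })
  outcome_table(ids, setNames(out, outcome_names))
}

#' Write an outcome table as TSV
#' @param x an [outcome_table()].
#' @param path output file path.
#' @export
write_outcomes <- function(x, path) {
  stopifnot(inherits(x, "outcome_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", names(x$outcomes)), collapse = "\t"), con)
  body <- vapply(seq_along(x$sample_ids), function(i)
    paste(c(x$sample_ids[i],
            vapply(x$outcomes, function(v) as.character(v[i]), character(1))),
          collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a patient graph
#'
#' GraphML output stores the soft-threshold power `beta` and the scale-free
#' fit `fit_r2` as graph attributes; the edge-list format is a three-column
#' (from, to, weight) TSV and keeps weights only.
#'
#' @param graph a [patient_graph()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(graph, "patient_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph_psn(graph)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    idx <- which(upper.tri(graph$weights), arr.ind = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("from\tto\tweight", con)
    writeLines(paste(graph$sample_ids[idx[, 1]], graph$sample_ids[idx[, 2]],
                     format_num(graph$weights[idx]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a patient graph written by [write_graph_file()]
#' @param path input file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return a [patient_graph()].
#' @export
read_graph_file <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    ids <- igraph::vertex_attr(ig, "name")
    if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(ig)))
    w <- igraph::as_adjacency_matrix(ig, attr = "weight", sparse = FALSE)
    dimnames(w) <- list(ids, ids)
    beta <- igraph::graph_attr(ig, "beta")
    fit_r2 <- igraph::graph_attr(ig, "fit_r2")
    patient_graph(w, beta = if (is.null(beta)) 1 else beta,
                  fit_r2 = if (is.null(fit_r2)) NA_real_ else fit_r2)
  } else {
    df <- read.delim(path, sep = "\t", colClasses = c("character", "character",
                                                      "numeric"))
    ids <- unique(c(df[[1]], df[[2]]))
    w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    w[cbind(df[[1]], df[[2]])] <- df[[3]]
    w[cbind(df[[2]], df[[1]])] <- df[[3]]
    patient_graph(w, beta = 1, fit_r2 = NA_real_)
  }
}

#' Write / read a samples-by-features topological feature matrix
#'
#' @param x a `topo_features` object (see [assemble_features()]) or any
#'   numeric matrix with sample rownames.
#' @param path file path.
#' @export
write_feature_matrix <- function(x, path) {
  vals <- if (inherits(x, "topo_features")) x$values else as.matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(vals)), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(vals)), function(i)
    paste(c(rownames(vals)[i], format_num(vals[i, ])), collapse = "\t"),
    character(1)), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
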