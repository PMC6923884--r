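# Assembly of the samples x features topological feature matrix from
# centrality blocks and module-membership indicators, with provenance
# tags, and leakage-safe z-score standardization.

#' Tag a feature block with its provenance
#'
#' @param x a `centrality_matrix`, a binary module-indicator matrix (from
#'   [module_indicator_features()]) or any samples x features numeric
#'   matrix with sample rownames.
#' @param dataset_tag cohort/platform tag (e.g. `"cohortA"`).
#' @param set `"centralities"` or `"modularities"`.
#' @return a `feature_block` list: `values`, `dataset_tag`, `set`.
#' @export
feature_block <- function(x, dataset_tag,
                          set = c("centralities", "modularities")) {
  set <- match.arg(set)
  vals <- if (inherits(x, "centrality_matrix")) x$values else as.matrix(x)
  if (is.null(rownames(vals))) stop("feature block needs sample rownames")
  structure(list(values = vals, dataset_tag = dataset_tag, set = set),
            class = "feature_block")
}

#' Assemble a topological feature matrix
#'
#' Horizontally concatenates feature blocks, keeping only the requested
#' set(s).  Feature names carry provenance as `<tag>|<set>|<name>`, so a
#' block concatenated with itself stays disambiguated by tag.  All blocks
#' must share sample ids and order.
#'
#' @param blocks list of [feature_block()]s.
#' @param set_choice `"centralities"`, `"modularities"` or `"both"`.
#' @return a `topo_features` list: `values` (n x d), `feature_names`,
#'   `sample_ids`, `set_choice`, `dataset_tags`, `standardized` flag.
#' @export
assemble_features <- function(blocks,
                              set_choice = c("centralities", "modularities",
                                             "both")) {
  set_choice <- match.arg(set_choice)
  keep <- if (set_choice == "both") blocks else
    Filter(function(b) b$set == set_choice, blocks)
  if (length(keep) == 0) stop("no feature blocks match set_choice")
  ids <- rownames(keep[[1]]$values)
  for (b in keep) {
    if (!identical(rownames(b$values), ids))
      stop("sample ids differ across feature blocks (tag '",
           b$dataset_tag, "')")
  }
  cols <- lapply(keep, function(b) {
    v <- b$values
    colnames(v) <- paste(b$dataset_tag, b$set, colnames(v), sep = "|")
    v
  })
  vals <- do.call(cbind, cols)
  structure(list(values = vals, feature_names = colnames(vals),
                 sample_ids = ids, set_choice = set_choice,
                 dataset_tags = unique(vapply(keep, `[[`, character(1),
                                              "dataset_tag")),
                 standardized = FALSE),
            class = "topo_features")
}

#' @export
print.topo_features <- function(x, ...) {
  cat(sprintf(
    "topo_features: %d samples x %d features (%s; datasets: %s)%s\n",
    nrow(x$values), ncol(x$values), x$set_choice,
    paste(x$dataset_tags, collapse = ", "),
    if (x$standardized) " [standardized]" else ""))
  invisible(x)
}

#' Standardize topological features (leakage-safe)
#'
#' Z-scores every feature using means and standard deviations estimated on
#' the `fit_ids` subset only (normally the training partition), then
#' applied to all rows.  Features with zero variance on the fit subset are
#' dropped with a warning.
#'
#' @param features a `topo_features` object.
#' @param fit_ids sample ids on which to estimate the scaler; default all.
#' @return the standardized `topo_features`, with the scaler recorded in
#'   the `scaler` element (`center`, `scale`, `feature_names`).
#' @export
standardize <- function(features, fit_ids = NULL) {
  stopifnot(inherits(features, "topo_features"))
  if (is.null(fit_ids)) fit_ids <- features$sample_ids
  if (length(fit_ids) == 0) stop("empty fit set")
  if (!all(fit_ids %in% features$sample_ids))
    stop("fit_ids not all present in feature matrix")
  fit <- features$values[fit_ids, , drop = FALSE]
  center <- colMeans(fit)
  scale_ <- apply(fit, 2, sd)
  drop <- scale_ == 0 | !is.finite(scale_)
  if (any(drop))
    warning(sum(drop), " zero-variance feature(s) dropped: ",
            paste(head(colnames(fit)[drop], 5), collapse = ", "))
  vals <- sweep(features$values[, !drop, drop = FALSE], 2, center[!drop])
  vals <- sweep(vals, 2, scale_[!drop], "/")
  out <- features
  out$values <- vals
  out$feature_names <- colnames(vals)
  out$standardized <- TRUE
  out$n_dropped <- sum(drop)
  out$scaler <- list(center = center[!drop], scale = scale_[!drop],
                     feature_names = colnames(vals))
  out
}

# apply a frozen scaler to a raw feature matrix (columns matched by name)
apply_scaler <- function(values, scaler) {
  missing_cols <- setdiff(scaler$feature_names, colnames(values))
  if (length(missing_cols))
    stop("features missing from external matrix: ",
         paste(head(missing_cols, 5), collapse = ", "))
  v <- values[, scaler$feature_names, drop = FALSE]
  sweep(sweep(v, 2, scaler$center), 2, scaler$scale, "/")
}

#' Extract topological features from an expression matrix in one call
#'
#' Convenience wrapper running the PSN construction and feature extraction
#' for one cohort: build the graph, compute the 12 centralities and
#' (optionally) spectral/blockmodel module indicators, and return the
#' unstandardized feature blocks.
#'
#' @param expr an [expression_matrix()] (after feature screening).
#' @param dataset_tag provenance tag for the blocks.
#' @param sets feature sets to compute: subset of
#'   `c("centralities", "modularities")`.
#' @param beta soft-threshold power, `"auto"` or numeric.
#' @param k_max,b_max module-count caps for spectral/blockmodel detection.
#' @param seed seed for the stochastic module fits.
#' @return list: `graph` (the [patient_graph()]), `blocks` (list of
#'   [feature_block()]s), `modules` (list of `module_assignment`s, possibly
#'   empty).
#' @export
extract_topology <- function(expr, dataset_tag = expr$platform_tag,
                             sets = c("centralities", "modularities"),
                             beta = "auto", k_max = 15, b_max = 20,
                             seed = 1) {
  sets <- match.arg(sets, several.ok = TRUE)
  graph <- build_psn(expr, beta = beta)
  blocks <- list()
  modules <- list()
  if ("centralities" %in% sets) {
    cent <- compute_centralities(graph)
    blocks <- c(blocks, list(feature_block(cent, dataset_tag,
                                           "centralities")))
  }
  if ("modularities" %in% sets) {
    spec <- spectral_modules(graph, k_max = k_max, seed = seed)
    sbm <- sbm_modules(graph, b_max = b_max, seed = seed)
    modules <- list(spectral = spec, sbm = sbm)
    ind <- cbind(module_indicator_features(spec),
                 module_indicator_features(sbm))
    blocks <- c(blocks, list(feature_block(ind, dataset_tag,
                                           "modularities")))
  }
  list(graph = graph, blocks = blocks, modules = modules)
}
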