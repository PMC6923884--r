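# Model scoring and comparison: balanced accuracy, one-way ANOVA with
# post-hoc Tukey tests on groups of model runs, best-model selection, and
# the frozen-model cross-cohort transfer harness.

#' Balanced accuracy
#'
#' Mean of the two per-class recalls (sensitivity and specificity),
#' insensitive to class imbalance: a constant majority-class predictor
#' scores 0.5.
#'
#' @param y_true binary 0/1 truth vector containing both classes.
#' @param y_pred binary 0/1 predictions of the same length.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(unique(y_true)) < 2)
    stop("y_true must contain both classes")
  recall1 <- mean(y_pred[y_true == 1] == 1)
  recall0 <- mean(y_pred[y_true == 0] == 0)
  (recall0 + recall1) / 2
}

#' Compare groups of model runs (one-way ANOVA + Tukey HSD)
#'
#' Groups records of balanced accuracies (e.g. by feature set or
#' architecture), runs a one-way ANOVA across groups, and reports Tukey
#' honest-significant-difference pairwise comparisons: the mean difference
#' in balanced accuracy per pair (delta bACC) with its 95% confidence
#' interval and adjusted p-value, flagged significant below `alpha`.
#'
#' @param records data.frame of evaluation records.
#' @param grouping name of the grouping column (default `"config_id"`).
#' @param value name of the bACC column (default `"bacc_valid"`).
#' @param alpha significance threshold (default 0.01).
#' @return a `group_comparison` list: `anova_p`, `pairs` (data.frame with
#'   `pair`, `delta_bacc`, `ci_lower`, `ci_upper`, `p_adj`, `significant`),
#'   `alpha`, `group_means`.
#' @export
compare_groups <- function(records, grouping = "config_id",
                           value = "bacc_valid", alpha = 0.01) {
  g <- factor(records[[grouping]])
  v <- records[[value]]
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (min(table(g)) < 2) stop("need at least 2 records per group")
  within_var <- tapply(v, g, var)
  if (all(within_var < 1e-300))
    stop("zero within-group variance in every group; ANOVA undefined")
  fit <- aov(v ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 0.95)$g
  pairs <- data.frame(pair = rownames(tk), delta_bacc = tk[, "diff"],
                      ci_lower = tk[, "lwr"], ci_upper = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(anova_p = anova_p, pairs = pairs, alpha = alpha,
                 group_means = tapply(v, g, mean)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: ANOVA p = %.3g (threshold %.2g); %d/%d pairs significant\n",
              x$anova_p, x$alpha, sum(x$pairs$significant), nrow(x$pairs)))
  invisible(x)
}

#' Select the best record by balanced accuracy
#'
#' Argmax of balanced accuracy within each scope (e.g. per feature set),
#' including across replicates.  Ties are broken deterministically by
#' simpler architecture (lower complexity) and then lower seed.
#'
#' @param records data.frame of evaluation records (as produced by
#'   [grid_search()]).
#' @param scope optional column name; one winner is returned per level.
#' @param value bACC column used for ranking (default `"bacc_valid"`).
#' @return one record row (or one per scope level), as a data.frame.
#' @export
best_model <- function(records, scope = NULL, value = "bacc_valid") {
  if (nrow(records) == 0) stop("no records")
  pick <- function(df) {
    complexity <- if ("complexity" %in% names(df)) df$complexity else 0
    seeds <- if ("seed" %in% names(df)) df$seed else seq_len(nrow(df))
    df[order(-df[[value]], complexity, seeds)[1], , drop = FALSE]
  }
  if (is.null(scope)) return(pick(records))
  out <- do.call(rbind, lapply(split(records, records[[scope]]), pick))
  rownames(out) <- NULL
  out
}

#' Score a frozen model on an external cohort
#'
#' Applies a trained model unchanged to topological features extracted from
#' an independent cohort (which has its own PSN and hence its own feature
#' extraction).  Only centrality features transfer across cohorts: module
#' identities are cohort-specific, so modularity features raise an error.
#' Columns are aligned by centrality metric name; standardization uses the
#' training cohort's frozen scaler by default.
#'
#' @param model a fitted `psn_model` (DNN, SVM or RF) trained on
#'   centralities of a single dataset.
#' @param external_features a `topo_features` of the external cohort
#'   (centralities, unstandardized).
#' @param external_y named binary outcome vector for the external cohort.
#' @param standardize_with `"external"` (z-score per cohort, mirroring the
#'   per-dataset feature normalization used at training time; default) or
#'   `"train"` (apply the training cohort's frozen scaler).  Per-cohort
#'   standardization absorbs graph-level shifts in centrality scales (e.g.
#'   the clustering coefficient's dependence on each graph's maximum
#'   weight) that a frozen scaler cannot.
#' @return balanced accuracy of the frozen model on the external cohort.
#' @export
external_validate <- function(model, external_features, external_y,
                              standardize_with = c("external", "train")) {
  standardize_with <- match.arg(standardize_with)
  stopifnot(inherits(external_features, "topo_features"))
  parse_metric <- function(nms) {
    parts <- strsplit(nms, "|", fixed = TRUE)
    set <- vapply(parts, function(p) p[max(1, length(p) - 1)], character(1))
    metric <- vapply(parts, function(p) p[length(p)], character(1))
    list(set = set, metric = metric)
  }
  mod_info <- parse_metric(model$feature_names)
  if (any(mod_info$set != "centralities"))
    stop("model uses modularity features, which are cohort-specific and do ",
         "not transfer; retrain with centralities only")
  if (length(unique(sub("\\|.*$", "", model$feature_names))) > 1)
    stop("model trained on concatenated datasets cannot transfer; ",
         "retrain on a single dataset's centralities")
  ext_info <- parse_metric(external_features$feature_names)
  if (any(ext_info$set != "centralities"))
    stop("external features must be centralities only")
  miss <- setdiff(mod_info$metric, ext_info$metric)
  if (length(miss))
    stop("external cohort lacks centrality metric(s): ",
         paste(miss, collapse = ", "))
  ext_vals <- external_features$values[,
    match(mod_info$metric, ext_info$metric), drop = FALSE]
  colnames(ext_vals) <- model$feature_names
  x <- if (standardize_with == "train") {
    if (is.null(model$scaler)) stop("model carries no scaler")
    apply_scaler(ext_vals, model$scaler)
  } else {
    scale(ext_vals)
  }
  pred <- predict(model, x)
  balanced_accuracy(external_y[rownames(ext_vals)], pred)
}
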