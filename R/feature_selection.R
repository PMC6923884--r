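# Per-feature two-sample Wilcoxon rank-sum screening against a binary
# outcome, computed on training samples only, with a top-fraction fallback
# when no feature clears the significance threshold.

#' Two-sided Wilcoxon rank-sum p-value per feature
#'
#' For each feature (column of `x_train`) tests whether its distribution
#' differs between the two outcome classes.  The exact rank-sum null
#' distribution is used for small tie-free groups; otherwise the normal
#' approximation with midrank tie correction and continuity correction
#' (the standard behaviour of [stats::wilcox.test()]).
#'
#' No multiple-testing correction is applied: features are screened at the
#' raw p-value, so the selected set is a liberal screen, not an
#' FDR-controlled discovery list.
#'
#' @param x_train samples x features numeric matrix (training samples only).
#' @param y_train binary 0/1 vector, one label per row of `x_train`; both
#'   classes must have at least 2 samples.
#' @return numeric vector of p-values in `[0, 1]`, one per feature.
#' @export
wilcoxon_pvalues <- function(x_train, y_train) {
  x_train <- as.matrix(x_train)
  y_train <- as.integer(y_train)
  if (length(y_train) != nrow(x_train))
    stop("y_train length must match rows of x_train")
  if (length(unique(y_train)) < 2)
    stop("y_train has a single class; need both classes to screen features")
  if (min(table(y_train)) < 2) stop("need at least 2 samples per class")
  g1 <- y_train == 1L
  apply(x_train, 2, function(v) {
    if (all(v == v[1])) return(1)  # degenerate: feature constant, no evidence
    suppressWarnings(
      wilcox.test(v[g1], v[!g1], alternative = "two.sided")$p.value)
  })
}

#' Select features by p-value threshold, with top-fraction fallback
#'
#' Keeps features with `P < alpha`.  When none qualify, the
#' `ceiling(fallback_frac * p)` smallest-p features are kept regardless of
#' their p-values (ties at the boundary resolved by feature index order).
#'
#' @param pvalues vector of per-feature p-values (finite).
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param fallback_frac fraction of features kept when nothing passes
#'   `alpha`; default 0.05.
#' @return a `selection_result` list: `pvalues`, `selected` (integer
#'   indices), `alpha`, `fallback_used`, `fallback_frac`.
#' @export
select_features <- function(pvalues, alpha = 0.05, fallback_frac = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(!is.finite(pvalues))) stop("pvalues must be finite")
  selected <- which(pvalues < alpha)
  fallback_used <- FALSE
  if (length(selected) == 0) {
    k <- ceiling(fallback_frac * length(pvalues))
    selected <- order(pvalues, seq_along(pvalues))[seq_len(k)]
    selected <- sort(selected)
    fallback_used <- TRUE
  }
  structure(list(pvalues = pvalues, selected = selected, alpha = alpha,
                 fallback_used = fallback_used, fallback_frac = fallback_frac),
            class = "selection_result")
}

#' Screen an expression matrix against one outcome using training samples
#'
#' Convenience wrapper: transposes the expression matrix to samples x
#' features, computes Wilcoxon p-values on the training subset only (the
#' leakage guard — test labels are never seen), applies [select_features()],
#' and returns the reduced expression matrix over all samples.
#'
#' @param expr an [expression_matrix()].
#' @param outcomes an [outcome_table()].
#' @param outcome_name outcome to screen against.
#' @param train_ids sample ids forming the training partition.
#' @param alpha,fallback_frac forwarded to [select_features()].
#' @return list: `expression` (reduced [expression_matrix()], all samples),
#'   `selection` (the `selection_result`).
#' @export
screen_features <- function(expr, outcomes, outcome_name, train_ids,
                            alpha = 0.05, fallback_frac = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  y <- outcome_vector(outcomes, outcome_name)
  if (!all(train_ids %in% expr$sample_ids))
    stop("train_ids not all present in expression matrix")
  x_train <- t(expr$values[, train_ids, drop = FALSE])
  pv <- wilcoxon_pvalues(x_train, y[train_ids])
  sel <- select_features(pv, alpha = alpha, fallback_frac = fallback_frac)
  red <- expression_matrix(expr$values[sel$selected, , drop = FALSE],
                           platform_tag = expr$platform_tag)
  list(expression = red, selection = sel)
}
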