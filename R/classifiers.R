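# SVM and random-forest baselines and the family-agnostic grid search with
# seeded replicates.  SVM and RF fits are delegated to e1071 and
# randomForest; class weights match the DNN's inverse-frequency scheme.

#' SVM hyper-parameter specification
#'
#' Cost and gamma follow the `2^(2p)` grid with integer `p` in `[-4, 4]`.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost,gamma kernel parameters (gamma ignored by the linear
#'   kernel).
#' @return an `svm_spec` list.
#' @export
svm_spec <- function(kernel = c("rbf", "linear"), cost = 1, gamma = 1) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "svm_spec")
}

#' The exponentially spaced SVM parameter grid `2^(2p)`, p integer in `[-4, 4]`
#' @param p_range integer exponents.
#' @return numeric vector of grid values.
#' @export
svm_param_grid <- function(p_range = -4:4) 2^(2 * p_range)

#' Random-forest hyper-parameter specification
#' @param n_trees number of trees, in `[100, 10000]`.
#' @param seed fit seed (forest growth is stochastic).
#' @return an `rf_spec` list.
#' @export
rf_spec <- function(n_trees = 500, seed = 1) {
  if (n_trees < 100 || n_trees > 10000)
    stop("n_trees must lie in [100, 10000]")
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "rf_spec")
}

#' Train an SVM / random forest on topological features
#'
#' Both use the training partition only, with inverse-frequency class
#' weights matching [class_weights()].  The SVM objective is convex, so a
#' single run per grid point suffices; RF is stochastic and is replicated
#' at the grid-search layer.
#'
#' @param features standardized `topo_features`.
#' @param y named binary outcome vector.
#' @param split a `split_assignment`.
#' @param spec an [svm_spec()] / [rf_spec()].
#' @return an `svm_model` / `rf_model` with a [predict()] method.
#' @export
train_svm <- function(features, y, split, spec) {
  stopifnot(inherits(features, "topo_features"), inherits(spec, "svm_spec"))
  x_train <- features$values[split$train_ids, , drop = FALSE]
  y_train <- factor(y[split$train_ids], levels = c(0, 1))
  cw <- class_weights(y[split$train_ids])
  fit <- e1071::svm(x_train, y_train,
                    kernel = if (spec$kernel == "rbf") "radial" else "linear",
                    cost = spec$cost, gamma = spec$gamma,
                    class.weights = cw, scale = FALSE)
  structure(list(spec = spec, fit = fit, feature_names = colnames(x_train),
                 scaler = features$scaler, family = "svm"),
            class = c("svm_model", "psn_model"))
}

#' @rdname train_svm
#' @export
train_rf <- function(features, y, split, spec) {
  stopifnot(inherits(features, "topo_features"), inherits(spec, "rf_spec"))
  x_train <- features$values[split$train_ids, , drop = FALSE]
  y_train <- factor(y[split$train_ids], levels = c(0, 1))
  cw <- class_weights(y[split$train_ids])
  fit <- with_seed(spec$seed,
    randomForest::randomForest(x_train, y_train, ntree = spec$n_trees,
                               classwt = cw))
  structure(list(spec = spec, fit = fit, feature_names = colnames(x_train),
                 scaler = features$scaler, family = "rf"),
            class = c("rf_model", "psn_model"))
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "topo_features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  p <- predict(object$fit, newdata)
  setNames(as.integer(as.character(p)), rownames(newdata))
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  if (inherits(newdata, "topo_features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  p <- predict(object$fit, newdata)
  setNames(as.integer(as.character(p)), rownames(newdata))
}

# score a fitted model on the evaluation and validation partitions
score_model <- function(model, features, y, split) {
  pe <- predict(model, features$values[split$eval_ids, , drop = FALSE])
  pv <- predict(model, features$values[split$valid_ids, , drop = FALSE])
  c(bacc_eval = balanced_accuracy(y[split$eval_ids], pe),
    bacc_valid = balanced_accuracy(y[split$valid_ids], pv))
}

# compact textual summary of a configuration, for result tables
describe_config <- function(family, cfg) {
  switch(family,
    dnn = sprintf("arch=[%s] opt=%s lr=%g drop=%g",
                  paste(cfg$hidden_sizes, collapse = ","), cfg$optimizer,
                  cfg$learning_rate, cfg$dropout),
    svm = sprintf("kernel=%s cost=%g gamma=%g", cfg$kernel, cfg$cost,
                  cfg$gamma),
    rf = sprintf("ntree=%d", cfg$n_trees))
}

dnn_complexity <- function(hidden_sizes)
  sum(hidden_sizes) + length(hidden_sizes)

#' Grid search with seeded replicates
#'
#' Trains one model per (configuration, replicate) and records evaluation-
#' and validation-partition balanced accuracies.  DNN and RF configurations
#' are replicated (default 10 times) with replicate seeds derived
#' deterministically from the master seed; the SVM problem is convex and
#' runs once per grid point.
#'
#' @param family `"dnn"`, `"svm"` or `"rf"`.
#' @param features standardized `topo_features`.
#' @param y named binary outcome vector.
#' @param split a `split_assignment`.
#' @param grid for `dnn`: a named list of vectors over `hidden_sizes`
#'   (list of integer vectors), `learning_rate`, `dropout`, `optimizer`,
#'   plus optional fixed fields (`epochs`, ...); for `svm`: over `kernel`,
#'   `cost`, `gamma`; for `rf`: over `n_trees`.
#' @param replicates replicates per configuration (default 10; forced to 1
#'   for SVM).
#' @param seed master seed from which replicate seeds are derived.
#' @param keep_models keep every fitted model (default: best only).
#' @param dataset_tag,feature_set provenance strings copied into records.
#' @return list: `records` (data.frame, one row per configuration x
#'   replicate), `best_model` (refit of the best validation-bACC record),
#'   `models` (when `keep_models`).
#' @export
grid_search <- function(family = c("dnn", "svm", "rf"), features, y, split,
                        grid = list(), replicates = 10, seed = 1,
                        keep_models = FALSE,
                        dataset_tag = paste(features$dataset_tags,
                                            collapse = "+"),
                        feature_set = features$set_choice) {
  family <- match.arg(family)
  configs <- expand_config_grid(family, grid)
  if (length(configs) == 0) stop("empty grid")
  if (family == "svm") replicates <- 1
  records <- list(); models <- list()
  for (ci in seq_along(configs)) {
    for (r in seq_len(replicates)) {
      rep_seed <- (seed * 100003L + ci * 1009L + r) %% 2147483647L
      cfg <- configs[[ci]]
      model <- switch(family,
        dnn = {
          sp <- do.call(dnn_spec, c(cfg, list(seed = rep_seed)))
          train_dnn(features, y, split, sp)
        },
        svm = train_svm(features, y, split, do.call(svm_spec, cfg)),
        rf = train_rf(features, y, split,
                      do.call(rf_spec, c(cfg, list(seed = rep_seed)))))
      sc <- score_model(model, features, y, split)
      key <- sprintf("c%d_r%d", ci, r)
      records[[key]] <- data.frame(
        family = family, config_id = ci,
        params = describe_config(family, cfg),
        complexity = if (family == "dnn") dnn_complexity(cfg$hidden_sizes)
                     else 0,
        replicate = r, seed = rep_seed,
        bacc_eval = sc[["bacc_eval"]], bacc_valid = sc[["bacc_valid"]],
        dataset = dataset_tag, feature_set = feature_set,
        stringsAsFactors = FALSE)
      if (keep_models) models[[key]] <- model
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  best_row <- best_model(records)
  best_cfg <- configs[[best_row$config_id]]
  best <- switch(family,
    dnn = train_dnn(features, y, split,
                    do.call(dnn_spec, c(best_cfg, list(seed = best_row$seed)))),
    svm = train_svm(features, y, split, do.call(svm_spec, best_cfg)),
    rf = train_rf(features, y, split,
                  do.call(rf_spec, c(best_cfg, list(seed = best_row$seed)))))
  list(records = records, best_model = best, best_record = best_row,
       models = if (keep_models) models)
}

# expand a named list of value vectors into a list of configuration lists
expand_config_grid <- function(family, grid) {
  defaults <- switch(family,
    dnn = list(hidden_sizes = list(c(8L, 4L)), learning_rate = 1e-3,
               dropout = 0.3, optimizer = "adam"),
    svm = list(kernel = "rbf", cost = 1, gamma = 1),
    rf = list(n_trees = 500))
  varying <- names(grid)[vapply(grid, length, integer(1)) > 0]
  for (nm in names(defaults))
    if (!nm %in% varying) grid[[nm]] <- defaults[[nm]]
  fixed <- grid[!names(grid) %in% c(names(defaults), "hidden_sizes")]
  axes <- grid[names(grid) %in% names(defaults)]
  if (!is.list(axes$hidden_sizes) && !is.null(axes$hidden_sizes))
    axes$hidden_sizes <- list(axes$hidden_sizes)
  idx <- do.call(expand.grid,
                 c(lapply(axes, seq_along), list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(idx)), function(i) {
    cfg <- lapply(names(axes), function(nm) {
      v <- axes[[nm]][[idx[i, nm]]]
      v
    })
    names(cfg) <- names(axes)
    c(cfg, fixed)
  })
}
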