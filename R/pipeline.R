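# End-to-end orchestration: expression matrices -> feature screening ->
# patient similarity graphs -> topological features -> stratified split ->
# grid-searched classifiers -> comparison tables, from a single seeded
# configuration.  Every intermediate artifact and every derived seed is
# written so any record is regenerable from the manifest alone.

#' Assemble a run configuration
#'
#' @param datasets named list of dataset entries; each entry is either
#'   `list(expression = <path or expression_matrix>)` or omitted entirely
#'   in favour of `synthetic`.
#' @param synthetic optional [cohort_config()]; when given, a synthetic
#'   cohort (or platform pair, if `platform_pair` is `TRUE`) is generated
#'   and used as the dataset(s).
#' @param platform_pair generate two platform views of the synthetic
#'   cohort.
#' @param outcomes path to an outcome TSV or an [outcome_table()]
#'   (ignored for synthetic data, which carries its own labels).
#' @param outcome_name outcome column to model (default `"event"`).
#' @param alpha Wilcoxon screening threshold.
#' @param feature_sets subset of `c("centralities", "modularities",
#'   "both")`.
#' @param concat_datasets also evaluate the concatenation of all datasets.
#' @param psn list of PSN settings (`beta`, `r2_target`).
#' @param module_caps list with `k_max` (spectral) and `b_max`
#'   (blockmodel).
#' @param grids named list of per-family grids (see [grid_search()]); only
#'   listed families are run.
#' @param replicates replicates per configuration.
#' @param seed master seed.
#' @param out_dir output directory (created); `NULL` disables writing.
#' @return a `run_config` list.
#' @export
run_config <- function(datasets = NULL, synthetic = NULL,
                       platform_pair = FALSE, outcomes = NULL,
                       outcome_name = "event", alpha = 0.05,
                       feature_sets = "centralities",
                       concat_datasets = FALSE,
                       psn = list(beta = "auto", r2_target = 0.8),
                       module_caps = list(k_max = 15, b_max = 20),
                       grids = list(dnn = list()), replicates = 10,
                       seed = 1, out_dir = NULL) {
  feature_sets <- match.arg(feature_sets,
                            c("centralities", "modularities", "both"),
                            several.ok = TRUE)
  if (is.null(datasets) && is.null(synthetic))
    stop("provide datasets or a synthetic cohort config")
  structure(list(datasets = datasets, synthetic = synthetic,
                 platform_pair = platform_pair, outcomes = outcomes,
                 outcome_name = outcome_name, alpha = alpha,
                 feature_sets = feature_sets,
                 concat_datasets = concat_datasets, psn = psn,
                 module_caps = module_caps, grids = grids,
                 replicates = replicates, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The YAML mirrors [run_config()] fields; a `synthetic:` mapping is passed
#' to [cohort_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(cohort_config, y$synthetic)
  if (!is.null(y$grids$dnn$hidden_sizes))
    y$grids$dnn$hidden_sizes <- lapply(y$grids$dnn$hidden_sizes, as.integer)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Execute a full run
#'
#' Stages: load or generate cohorts; Wilcoxon screening on the training
#' partition only; PSN construction over all samples of each cohort (the
#' transductive step: the graph includes training and test samples, but
#' never sees labels); topological feature extraction; assembly and
#' train-fitted standardization per feature-set configuration; grid search
#' per requested family; best-model selection and group comparison.
#' Deterministic given the master seed.
#'
#' @param config a [run_config()].
#' @return a `run_report`: `records` (all evaluation records), `best`
#'   (best record per dataset x feature-set configuration), `comparison`
#'   (ANOVA/Tukey across configurations, when >= 2), `models` (best model
#'   per configuration), `graphs`, `selections`, `split`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  cohorts <- stage("load", load_cohorts(config))
  y <- outcome_vector(cohorts$outcomes, config$outcome_name)
  split <- stage("split",
                 stratified_split(y, seed = config$seed))

  selections <- list(); graphs <- list(); blocks <- list()
  for (tag in names(cohorts$expression)) {
    expr <- cohorts$expression[[tag]]
    scr <- stage(paste0("select:", tag),
                 screen_features(expr, cohorts$outcomes, config$outcome_name,
                                 split$train_ids, alpha = config$alpha))
    selections[[tag]] <- scr$selection
    want_mod <- any(config$feature_sets %in% c("modularities", "both"))
    topo <- stage(paste0("topology:", tag),
                  extract_topology(scr$expression, dataset_tag = tag,
                                   sets = c("centralities",
                                            if (want_mod) "modularities"),
                                   beta = config$psn$beta,
                                   k_max = config$module_caps$k_max,
                                   b_max = config$module_caps$b_max,
                                   seed = config$seed))
    graphs[[tag]] <- topo$graph
    blocks[[tag]] <- topo$blocks
    if (!is.null(out_dir)) {
      write_expression_matrix(scr$expression,
                              file.path(out_dir,
                                        paste0("selected_", tag, ".tsv")))
      write_graph_file(topo$graph,
                       file.path(out_dir, paste0("psn_", tag, ".graphml")))
    }
  }

  # dataset combinations: each cohort alone, plus the concatenation
  combos <- as.list(names(blocks))
  if (config$concat_datasets && length(blocks) > 1)
    combos <- c(combos, list(names(blocks)))
  records <- list(); models <- list()
  for (combo in combos) {
    combo_tag <- paste(combo, collapse = "+")
    combo_blocks <- unlist(blocks[combo], recursive = FALSE, use.names = FALSE)
    for (fs in config$feature_sets) {
      feats <- assemble_features(combo_blocks, set_choice = fs)
      feats <- standardize(feats, fit_ids = split$train_ids)
      if (!is.null(out_dir))
        write_feature_matrix(feats,
          file.path(out_dir, sprintf("topo_%s_%s.tsv", combo_tag, fs)))
      for (fam in names(config$grids)) {
        key <- sprintf("%s|%s|%s", combo_tag, fs, fam)
        gs <- stage(paste0("train:", key),
                    grid_search(fam, feats, y, split,
                                grid = config$grids[[fam]],
                                replicates = config$replicates,
                                seed = config$seed,
                                dataset_tag = combo_tag, feature_set = fs))
        records[[key]] <- gs$records
        models[[key]] <- gs$best_model
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  records$configuration <- paste(records$dataset, records$feature_set,
                                 sep = "|")
  best <- best_model(records, scope = "configuration")
  comparison <- NULL
  if (length(unique(records$configuration)) >= 2 &&
      all(table(records$configuration) >= 2)) {
    comparison <- tryCatch(
      compare_groups(records, grouping = "configuration"),
      error = function(e) NULL)
  }
  manifest <- list(seed = config$seed, outcome = config$outcome_name,
                   alpha = config$alpha, feature_sets = config$feature_sets,
                   n_samples = length(y),
                   split_sizes = vapply(split[c("train_ids", "eval_ids",
                                                "valid_ids")],
                                        length, integer(1)),
                   betas = vapply(graphs, `[[`, numeric(1), "beta"),
                   fit_r2 = vapply(graphs, `[[`, numeric(1), "fit_r2"),
                   replicate_seeds = sort(unique(records$seed)),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("psntopo")))
  if (!is.null(out_dir)) {
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(best, file.path(out_dir, "best_models.csv"),
                     row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison$pairs,
                       file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(records = records, best = best, comparison = comparison,
                 models = models, graphs = graphs, selections = selections,
                 split = split, manifest = manifest),
            class = "run_report")
}

load_cohorts <- function(config) {
  if (!is.null(config$synthetic)) {
    if (config$platform_pair) {
      pp <- generate_platform_pair(config$synthetic)
      return(list(expression = list(platform_A = pp$view_a,
                                    platform_B = pp$view_b),
                  outcomes = pp$outcomes))
    }
    co <- generate_cohort(config$synthetic)
    return(list(expression = list(synthetic = co$expression),
                outcomes = co$outcomes))
  }
  exprs <- lapply(config$datasets, function(d) {
    if (inherits(d$expression, "expression_matrix")) d$expression
    else read_expression_matrix(d$expression)
  })
  outc <- config$outcomes
  if (!inherits(outc, "outcome_table"))
    outc <- read_outcomes(outc,
                          expected_ids = exprs[[1]]$sample_ids)
  # restrict and order outcomes to the expression samples
  ids <- exprs[[1]]$sample_ids
  keep <- match(ids, outc$sample_ids)
  outc <- outcome_table(outc$sample_ids[keep],
                        lapply(outc$outcomes, function(v) v[keep]))
  list(expression = exprs, outcomes = outc)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d records over %d configuration(s)\n",
              nrow(x$records), length(unique(x$records$configuration))))
  b <- x$best
  for (i in seq_len(nrow(b)))
    cat(sprintf("  best %-30s bACC(valid) = %.3f  [%s]\n",
                b$configuration[i], b$bacc_valid[i], b$params[i]))
  invisible(x)
}
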