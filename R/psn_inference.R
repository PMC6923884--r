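# Patient similarity network construction: pairwise Pearson correlation of
# patient profiles, rescaled into positive edge weights by a WGCNA-style
# signed soft threshold, with the power chosen by the scale-free topology
# criterion.  The graph is transductive: it is built from all samples of a
# cohort (training and test alike) and never sees outcome labels.

#' Patient graph container
#'
#' Fully connected weighted graph over samples: symmetric weight matrix with
#' zero diagonal and strictly positive off-diagonal weights in `(0, 1]`,
#' plus the soft-threshold power used to build it and the scale-free fit R2.
#'
#' @param weights symmetric n x n numeric matrix, zero diagonal,
#'   off-diagonal entries in `(0, 1]`.
#' @param beta soft-threshold power (>= 1).
#' @param sample_ids sample identifiers (taken from `rownames` if `NULL`).
#' @param fit_r2 scale-free fit R2 recorded on the graph.
#' @return an object of class `patient_graph`.
#' @export
patient_graph <- function(weights, beta = 1, sample_ids = NULL,
                          fit_r2 = NA_real_) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("self-weights must be zero")
  off <- weights[upper.tri(weights)]
  if (n > 1 && (any(off <= 0) || any(off > 1)))
    stop("off-diagonal weights must lie in (0, 1]")
  if (is.null(sample_ids)) sample_ids <- rownames(weights)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  dimnames(weights) <- list(sample_ids, sample_ids)
  structure(list(weights = weights, beta = beta, sample_ids = sample_ids,
                 fit_r2 = fit_r2),
            class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat(sprintf("patient_graph: %d nodes, beta = %s, scale-free fit R2 = %s\n",
              length(x$sample_ids), format(x$beta),
              format(round(x$fit_r2, 3))))
  invisible(x)
}

# igraph view of a patient graph (undirected, weighted, graph attrs kept)
as_igraph_psn <- function(graph) {
  ig <- igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::V(ig)$name <- graph$sample_ids
  ig <- igraph::set_graph_attr(ig, "beta", graph$beta)
  igraph::set_graph_attr(ig, "fit_r2", graph$fit_r2)
}

#' Pairwise Pearson correlation between patient profiles
#'
#' @param x samples x features matrix, or an [expression_matrix()]
#'   (transposed internally).
#' @return a `correlation_matrix`: symmetric with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) x <- t(x$values)
  x <- as.matrix(x)
  vars <- apply(x, 1, var)
  if (any(vars == 0))
    stop("constant profile for sample(s): ",
         paste(rownames(x)[vars == 0], collapse = ", "))
  r <- cor(t(x))
  diag(r) <- 1
  structure(list(values = r, sample_ids = rownames(x)),
            class = "correlation_matrix")
}

#' Signed soft-threshold adjacency
#'
#' Rescales correlations into positive edge weights with the signed-network
#' transform `s_ij = (1 + r_ij) / 2`, `a_ij = s_ij ^ beta`.  A correlation
#' of exactly -1 would give weight 0; it is clamped to `eps` so the graph
#' stays literally fully connected.
#'
#' @param cor a `correlation_matrix` from [pearson_matrix()].
#' @param beta soft-threshold power (>= 1).
#' @param eps smallest allowed positive weight (default 1e-12).
#' @return a [patient_graph()] (fit_r2 left `NA`; see [scale_free_fit()]).
#' @export
adjacency <- function(cor, beta, eps = 1e-12) {
  stopifnot(inherits(cor, "correlation_matrix"))
  if (beta < 1) stop("beta must be >= 1")
  s <- (1 + cor$values) / 2
  a <- s^beta
  a <- pmax(a, eps)
  diag(a) <- 0
  patient_graph(a, beta = beta, sample_ids = cor$sample_ids)
}

#' Scale-free topology fit of a weighted degree distribution
#'
#' The standard WGCNA scale-free fit index: weighted degrees are cut into
#' `n_bins` equal-width bins, each non-empty bin contributes its mean
#' degree and its occupancy frequency, and the reported R2 is that of the
#' linear regression of log10(frequency) on log10(mean bin degree).  With
#' fewer than 3 usable bins (e.g. the equal-weight complete graph, a
#' single degree value) the fit is undefined and a flagged `NA` is
#' returned.
#'
#' @param graph a [patient_graph()] (or a numeric vector of weighted
#'   degrees).
#' @param n_bins number of degree bins (default 10).
#' @return a list: `r2` (numeric or `NA`), `degenerate` (flag), `fit_table`
#'   (data.frame of bin mean log-degrees and log-frequencies).
#' @export
scale_free_fit <- function(graph, n_bins = 10) {
  k <- if (inherits(graph, "patient_graph")) rowSums(graph$weights) else graph
  k <- k[k > 0]
  if (length(unique(round(k, 12))) < 3)
    return(list(r2 = NA_real_, degenerate = TRUE, fit_table = NULL))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  bin[bin == 0] <- 1L
  freq <- tabulate(bin, nbins = n_bins)
  centers <- vapply(seq_len(n_bins),
                    function(b) mean(k[bin == b]), numeric(1))
  keep <- freq > 0 & centers > 0
  if (sum(keep) < 3)
    return(list(r2 = NA_real_, degenerate = TRUE, fit_table = NULL))
  df <- data.frame(log_k = log10(centers[keep]),
                   log_freq = log10(freq[keep] / length(k)))
  fit <- stats::lm(log_freq ~ log_k, data = df)
  r2 <- summary(fit)$r.squared
  list(r2 = r2, degenerate = FALSE, fit_table = df)
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' For each candidate power computes the adjacency, its weighted degrees and
#' the scale-free fit R2, and returns the smallest power whose R2 reaches
#' `r2_target`; if none does, the power with the largest R2.  A degenerate
#' degree distribution (all degrees equal, e.g. all correlations 1) returns
#' beta = 1 with a warning flag.
#'
#' @param cor a `correlation_matrix`.
#' @param candidate_powers integer powers to scan (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins degree bins for the fit.
#' @return list: `beta`, `fit_r2`, `degenerate`, `fit_table` (data.frame of
#'   power and R2 per candidate).
#' @export
soft_threshold_power <- function(cor, candidate_powers = 1:20,
                                 r2_target = 0.8, n_bins = 10) {
  stopifnot(inherits(cor, "correlation_matrix"))
  if (length(cor$sample_ids) < 10) stop("need at least 10 samples")
  r2s <- vapply(candidate_powers, function(b) {
    g <- adjacency(cor, beta = b)
    scale_free_fit(g, n_bins = n_bins)$r2
  }, numeric(1))
  tab <- data.frame(power = candidate_powers, r2 = r2s)
  if (all(is.na(r2s))) {
    warning("degenerate degree distribution; falling back to beta = 1")
    return(list(beta = 1, fit_r2 = NA_real_, degenerate = TRUE,
                fit_table = tab))
  }
  hit <- which(!is.na(r2s) & r2s >= r2_target)
  pick <- if (length(hit)) hit[1] else which.max(r2s)
  list(beta = candidate_powers[pick], fit_r2 = r2s[pick], degenerate = FALSE,
       fit_table = tab)
}

#' Build a patient similarity network from an expression matrix
#'
#' Full construction: Pearson correlation of all patient profiles, power
#' selection by the scale-free criterion (unless `beta` is given), signed
#' soft-threshold adjacency, with the achieved fit R2 recorded on the graph.
#'
#' By default each feature is z-scored across samples before profiles are
#' correlated.  Inter-sample correlations are otherwise dominated by the
#' fixed per-feature mean/scale profile (probe affinities, platform
#' baselines), which is shared by every pair of patients and masks the
#' biological contrast; feature standardization is the standard remedy for
#' sample-correlation networks and is unsupervised, so it leaks no labels.
#'
#' @param expr an [expression_matrix()] (typically after feature screening).
#' @param beta `"auto"` (scale-free criterion) or a numeric power >= 1.
#' @param candidate_powers,r2_target forwarded to [soft_threshold_power()].
#' @param center_features z-score features across samples before
#'   correlating profiles (default `TRUE`).
#' @return a [patient_graph()].
#' @export
build_psn <- function(expr, beta = "auto", candidate_powers = 1:20,
                      r2_target = 0.8, center_features = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  vals <- expr$values
  if (center_features) {
    sds <- apply(vals, 1, sd)
    sds[sds == 0] <- 1
    vals <- (vals - rowMeans(vals)) / sds
  }
  cm <- pearson_matrix(t(vals))
  if (identical(beta, "auto")) {
    sel <- soft_threshold_power(cm, candidate_powers, r2_target)
    b <- sel$beta
  } else {
    b <- as.numeric(beta)
  }
  g <- adjacency(cm, beta = b)
  g$fit_r2 <- scale_free_fit(g)$r2
  g
}
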