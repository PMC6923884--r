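# Graph module detection on the patient similarity network: spectral
# clustering with automatic selection of the number of modules by the
# eigengap heuristic, and a weighted stochastic blockmodel with the number
# of blocks chosen by a minimum-description-length style criterion.
# Every detected module later becomes one binary membership feature.

module_assignment <- function(labels, method, objective_trace,
                              sample_ids = names(labels)) {
  k <- length(unique(labels))
  labels <- as.integer(factor(labels)) - 1L   # relabel to 0..k-1
  structure(list(labels = setNames(labels, sample_ids), k = k,
                 method = method, objective_trace = objective_trace),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment (%s): %d modules over %d samples\n",
              x$method, x$k, length(x$labels)))
  invisible(x)
}

#' Spectral clustering with eigengap model selection
#'
#' Normalized-Laplacian spectral clustering.  The number of modules k is
#' the position of the largest gap among the ordered Laplacian eigenvalues
#' within `2..k_max`; samples are clustered by seeded k-means on the
#' row-normalized embedding of the first k eigenvectors.
#'
#' @param graph a [patient_graph()].
#' @param k_max largest number of modules considered (default 15; must be
#'   < n).
#' @param seed seed for the embedding k-means.
#' @return a `module_assignment` with `objective_trace` holding the
#'   eigengap per candidate k.
#' @export
spectral_modules <- function(graph, k_max = 15, seed = 1) {
  stopifnot(inherits(graph, "patient_graph"))
  w <- graph$weights
  n <- nrow(w)
  if (n <= k_max) stop("need n > k_max")
  d_inv_sqrt <- 1 / sqrt(rowSums(w))
  l_sym <- diag(n) - (d_inv_sqrt * w) %*% diag(d_inv_sqrt)
  eig <- eigen((l_sym + t(l_sym)) / 2, symmetric = TRUE)
  lambda <- rev(eig$values)                 # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  n_comp <- sum(lambda < 1e-10)
  if (n_comp > k_max)
    stop("graph has ", n_comp, " disconnected components, more than k_max")
  ks <- 2:k_max
  gaps <- lambda[ks + 1] - lambda[ks]
  k <- ks[which.max(gaps)]
  u <- vecs[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  u <- u / ifelse(norms > 0, norms, 1)
  km <- with_seed(seed, kmeans(u, centers = k, nstart = 10, iter.max = 100))
  module_assignment(km$cluster, "spectral",
                    data.frame(k = ks, eigengap = gaps),
                    sample_ids = graph$sample_ids)
}

# membership one-hot matrix
membership_matrix <- function(labels, b) {
  m <- matrix(0, length(labels), b)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

# Description-length style objective for the Gaussian weighted blockmodel:
# each block pair carries its own mean and variance (2 parameters per
# cell), the labels cost n*log(B) nats, and parameters pay the usual
# (log m)/2-per-parameter BIC rate on m = n(n-1)/2 weight observations.
# Smaller is better.
wsbm_objective <- function(cell_ll, n_pairs, b, n) {
  cell_ll + b * (b + 1) * log(n_pairs) + n * log(b)
}

# fit a B-block Gaussian weighted blockmodel by seeded k-means
# initialization on the (optionally degree-corrected) weight rows plus
# greedy single-node reassignment passes; returns labels and the objective
wsbm_fit_b <- function(wn, b, seed, max_passes = 10) {
  n <- nrow(wn)
  pair_mask <- 1 - diag(n)
  w2 <- wn^2
  objective_of <- function(labels) {
    m <- membership_matrix(labels, b)
    s <- t(m) %*% wn %*% m            # block-pair weight sums (doubled)
    s2 <- t(m) %*% w2 %*% m
    cnt <- t(m) %*% pair_mask %*% m
    keep <- cnt > 0
    rss <- pmax(s2[keep] - s[keep]^2 / cnt[keep], 0)
    # -2 log-likelihood up to constants, per-cell variance, unordered pairs
    cell_ll <- sum(cnt[keep] / 2 *
                     log(pmax(rss / cnt[keep], 1e-12)))
    wsbm_objective(cell_ll, n * (n - 1) / 2, b, n)
  }
  labels <- if (b == 1) rep(1L, n) else
    with_seed(seed, suppressWarnings(
      kmeans(wn, centers = b, nstart = 5, iter.max = 50)$cluster))
  obj <- objective_of(labels)
  if (b > 1) {
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (v in seq_len(n)) {
        cur <- labels[v]
        for (cand in setdiff(seq_len(b), cur)) {
          labels[v] <- cand
          o <- objective_of(labels)
          if (o < obj - 1e-9) { obj <- o; cur <- cand; improved <- TRUE }
          else labels[v] <- cur
        }
      }
      if (!improved) break
    }
  }
  list(labels = labels, objective = obj)
}

#' Weighted stochastic blockmodel with automatic block count
#'
#' Fits a Gaussian weighted blockmodel (optionally degree-corrected by
#' rescaling each weight by the endpoint strengths) for an increasing
#' number of blocks B and selects the B minimizing a minimum-description-
#' length style objective; the scan stops early after `patience` candidate
#' B values without improvement.  The fit is stochastic: `n_restarts`
#' seeded restarts are run per B and the best objective kept.
#'
#' @param graph a [patient_graph()].
#' @param b_max largest number of blocks considered (default 50).
#' @param seed master seed for the restarts.
#' @param n_restarts restarts per candidate B (default 10).
#' @param degree_correct rescale weights by endpoint strengths first.
#' @param patience stop after this many candidate B without improvement.
#' @return a `module_assignment` with `objective_trace` holding the
#'   objective per candidate B actually evaluated.
#' @export
sbm_modules <- function(graph, b_max = 50, seed = 1, n_restarts = 10,
                        degree_correct = TRUE, patience = 3) {
  stopifnot(inherits(graph, "patient_graph"))
  if (b_max < 2) stop("b_max must be >= 2")
  w <- graph$weights
  n <- nrow(w)
  if (n < 10) stop("need at least 10 samples")
  wn <- w
  if (degree_correct) {
    s <- rowSums(w)
    wn <- w / sqrt(outer(s, s))
    wn <- wn / max(wn)
  }
  best <- NULL
  trace_b <- integer(0); trace_obj <- numeric(0)
  since_improve <- 0
  for (b in seq_len(min(b_max, n - 1))) {
    fits <- lapply(seq_len(if (b == 1) 1 else n_restarts), function(r)
      wsbm_fit_b(wn, b, seed = (seed * 1000L + b * 37L + r) %% 2147483647L))
    objs <- vapply(fits, `[[`, numeric(1), "objective")
    fit <- fits[[which.min(objs)]]
    trace_b <- c(trace_b, b); trace_obj <- c(trace_obj, fit$objective)
    if (is.null(best) || fit$objective < best$objective) {
      best <- c(fit, list(b = b)); since_improve <- 0
    } else {
      since_improve <- since_improve + 1
      if (since_improve >= patience) break
    }
  }
  module_assignment(best$labels, "sbm",
                    data.frame(b = trace_b, objective = trace_obj),
                    sample_ids = graph$sample_ids)
}

#' Binary module-membership indicator features
#'
#' One column per detected module; entry 1 for members, 0 otherwise, so
#' every row sums to exactly 1.
#'
#' @param assignment a `module_assignment`.
#' @return n x k binary matrix with sample rownames and columns
#'   `<method>_module_<j>`.
#' @export
module_indicator_features <- function(assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  m <- membership_matrix(assignment$labels + 1L, assignment$k)
  dimnames(m) <- list(names(assignment$labels),
                      sprintf("%s_module_%d", assignment$method,
                              seq_len(assignment$k) - 1L))
  m
}
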