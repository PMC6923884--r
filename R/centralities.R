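# Twelve per-patient centrality metrics on the weighted, fully connected
# patient similarity network.  Conventions for similarity weights a_ij:
# shortest-path metrics (closeness, load) use the induced distance
# d_ij = 1 / a_ij; current-flow metrics treat a_ij as an electrical
# conductance; spectral metrics (eigenvector, Katz, HITS, PageRank) act on
# the weight matrix directly.

POWER_TOL <- 1e-10
POWER_MAXIT <- 10000

#' Compute the twelve centrality metrics of a patient graph
#'
#' Returns one column per metric, in a fixed canonical order:
#' `weighted_degree`, `closeness`, `currentflow_closeness`,
#' `currentflow_betweenness`, `eigenvector`, `katz`, `hits`, `pagerank`,
#' `load`, `clustering_coef`, `iterative_weighted_degree`,
#' `iterative_clustering_coef`.  The fixed 12-column layout is what makes
#' feature spaces comparable across cohorts regardless of the original
#' feature count.
#'
#' @param graph a [patient_graph()].
#' @return a `centrality_matrix`: list with `values` (n x 12 matrix, all
#'   finite), `metric_names`, `sample_ids`.
#' @export
compute_centralities <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  w <- graph$weights
  n <- nrow(w)
  ig <- as_igraph_psn(graph)
  dist_w <- 1 / igraph::E(ig)$weight
  dmat <- igraph::distances(ig, weights = dist_w)

  vals <- matrix(NA_real_, n, length(CENTRALITY_METRICS),
                 dimnames = list(graph$sample_ids, CENTRALITY_METRICS))
  vals[, "weighted_degree"] <- rowSums(w)
  vals[, "closeness"] <- (n - 1) / rowSums(dmat)
  vals[, "currentflow_closeness"] <- currentflow_closeness(w)
  vals[, "currentflow_betweenness"] <- currentflow_betweenness(w)
  vals[, "eigenvector"] <- centrality_guard("eigenvector",
    igraph::eigen_centrality(ig, weights = igraph::E(ig)$weight,
                             options = list(maxiter = POWER_MAXIT))$vector)
  vals[, "katz"] <- katz_centrality(w)
  vals[, "hits"] <- centrality_guard("hits", hits_hub_scores(ig))
  vals[, "pagerank"] <- centrality_guard("pagerank",
    igraph::page_rank(ig, weights = igraph::E(ig)$weight,
                      damping = 0.85)$vector)
  vals[, "load"] <- load_centrality(w, dmat)
  vals[, "clustering_coef"] <- weighted_clustering(w)
  vals[, "iterative_weighted_degree"] <-
    iterative_centrality(graph, "weighted_degree")
  vals[, "iterative_clustering_coef"] <-
    iterative_centrality(graph, "clustering_coef")
  if (any(!is.finite(vals)))
    stop("non-finite centrality values for metric(s): ",
         paste(colnames(vals)[colSums(!is.finite(vals)) > 0], collapse = ", "))
  structure(list(values = vals, metric_names = CENTRALITY_METRICS,
                 sample_ids = graph$sample_ids),
            class = "centrality_matrix")
}

centrality_guard <- function(metric, value) {
  v <- tryCatch(value, error = function(e)
    stop(metric, ": solver failed to converge (", conditionMessage(e), ")"))
  if (any(!is.finite(v))) stop(metric, ": solver returned non-finite values")
  v
}

# hub scores; on an undirected graph hub and authority scores coincide
hits_hub_scores <- function(ig) {
  if (exists("hits_scores", where = asNamespace("igraph"))) {
    igraph::hits_scores(ig, weights = igraph::E(ig)$weight)$hub
  } else {
    igraph::hub_score(ig, weights = igraph::E(ig)$weight)$vector
  }
}

# Moore-Penrose pseudoinverse of the graph Laplacian via the rank-one
# correction (L + J/n)^-1 - J/n, valid for connected graphs
laplacian_pinv <- function(w) {
  n <- nrow(w)
  l <- diag(rowSums(w)) - w
  j <- matrix(1 / n, n, n)
  solve(l + j) - j
}

# current-flow (information) closeness: (n-1) / sum_j R_ij with effective
# resistance R_ij = T_ii + T_jj - 2 T_ij, T the Laplacian pseudoinverse
currentflow_closeness <- function(w) {
  n <- nrow(w)
  t_ <- laplacian_pinv(w)
  d <- diag(t_)
  r <- outer(d, d, "+") - 2 * t_
  (n - 1) / rowSums(r)
}

# current-flow betweenness (random-walk betweenness): average over
# source-sink pairs (s, t) not containing i of the current through i,
# I_i = (1/2) sum_j a_ij |V_i - V_j| for unit current injected at s and
# extracted at t.  Normalized by the (n-1)(n-2)/2 pairs excluding i.
currentflow_betweenness <- function(w) {
  n <- nrow(w)
  if (n < 3) return(rep(0, n))
  t_ <- laplacian_pinv(w)
  bw <- numeric(n)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1]; j <- idx[e, 2]
    d <- t_[i, ] - t_[j, ]                     # V_i - V_j for every pair
    # sum over all pairs s<t of |d_s - d_t| via the sorted-accumulation
    # identity sum_{s<t} |d_s - d_t| = sum_k (2k - n - 1) d_(k)
    ds <- sort(d)
    total <- sum((2 * seq_len(n) - n - 1) * ds)
    excl_i <- sum(abs(d[i] - d[-i]))           # pairs containing i
    excl_j <- sum(abs(d[j] - d[-j]))
    bw[i] <- bw[i] + w[i, j] * (total - excl_i)
    bw[j] <- bw[j] + w[i, j] * (total - excl_j)
  }
  bw / 2 / ((n - 1) * (n - 2) / 2)
}

# Katz centrality: solve (I - alpha A) x = 1 with alpha = 0.9 / lambda_max,
# reported with unit Euclidean norm
katz_centrality <- function(w, alpha_frac = 0.9) {
  n <- nrow(w)
  lmax <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
  if (lmax <= 0) stop("katz: non-positive spectral radius")
  alpha <- alpha_frac / lmax
  x <- solve(diag(n) - alpha * w, rep(1, n))
  x / sqrt(sum(x^2))
}

# load centrality: packet-routing betweenness.  A unit packet travels from
# each source s to each target t along shortest paths, dividing equally
# among shortest-path predecessors at every branch; a node's load is the
# total through-traffic over all ordered (s, t) pairs, divided by
# (n-1)(n-2).
load_centrality <- function(w, dmat = NULL, tol = 1e-10) {
  n <- nrow(w)
  if (n < 3) return(rep(0, n))
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  if (is.null(dmat)) {
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    dmat <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  }
  load <- numeric(n)
  for (s in seq_len(n)) {
    ds <- dmat[s, ]
    # predecessors of v on shortest s->v paths: u with d(s,u) + len(u,v) = d(s,v)
    amt <- rep(1, n)
    amt[s] <- 0
    for (v in order(ds, decreasing = TRUE)) {
      if (v == s || amt[v] == 0) next
      preds <- which(abs(ds + len[, v] - ds[v]) <= tol * max(1, ds[v]))
      if (length(preds) == 0) next        # unreachable (cannot happen here)
      amt[preds] <- amt[preds] + amt[v] / length(preds)
    }
    # through-traffic excludes each node's own incoming packet
    contrib <- amt - 1
    contrib[s] <- 0
    load <- load + pmax(contrib, 0)
  }
  load / ((n - 1) * (n - 2))
}

# local clustering coefficient for weighted graphs (geometric-mean triangle
# intensity): c_i = sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1)),
# weights scaled by the maximum weight, k_i the number of neighbours
weighted_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  a <- (w / mx)^(1 / 3)
  num <- diag(a %*% a %*% a)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  cc
}

#' Iterative (peeling) centrality
#'
#' Repeatedly computes the base metric on the current subgraph, records the
#' top-scoring node's value as its feature, removes that node, and
#' continues until the graph is empty.  Each node's feature is its score at
#' removal time; ties are broken by node index order.
#'
#' @param graph a [patient_graph()].
#' @param base `"weighted_degree"` or `"clustering_coef"`.
#' @return numeric vector of length n, named by sample id.
#' @export
iterative_centrality <- function(graph,
                                 base = c("weighted_degree",
                                          "clustering_coef")) {
  stopifnot(inherits(graph, "patient_graph"))
  base <- match.arg(base)
  metric <- switch(base, weighted_degree = rowSums,
                   clustering_coef = weighted_clustering)
  w <- graph$weights
  n <- nrow(w)
  out <- setNames(numeric(n), graph$sample_ids)
  alive <- seq_len(n)
  while (length(alive) > 0) {
    sub <- w[alive, alive, drop = FALSE]
    score <- if (length(alive) == 1) 0 else metric(sub)
    # ties (exact or to rounding noise) resolved by node index order
    top <- which(score >= max(score) - 1e-9 * max(1, abs(max(score))))[1]
    out[alive[top]] <- score[top]
    alive <- alive[-top]
  }
  out
}
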