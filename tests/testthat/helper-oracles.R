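# Definition-level oracle implementations used to cross-check the package's
# centrality code, plus small fixture builders.  Everything here is written
# directly from the metric definitions (loops, per-pair linear solves,
# exhaustive enumeration) and shares no code with the implementation.

random_weighted_graph <- function(n, seed) {
  w <- matrix(0, n, n)
  set.seed(seed)
  vals <- runif(n * (n - 1) / 2, 0.05, 1)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  patient_graph(w, beta = 1)
}

oracle_weighted_degree <- function(w) rowSums(w)

# all-pairs shortest paths by Floyd-Warshall on distances 1/w
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_closeness <- function(w) {
  d <- oracle_distances(w)
  (nrow(w) - 1) / rowSums(d)
}

# potentials for unit current injected at s and extracted at t, ground t
oracle_potentials <- function(w, s, t) {
  n <- nrow(w)
  lap <- diag(rowSums(w)) - w
  b <- rep(0, n); b[s] <- 1; b[t] <- -1
  v <- rep(0, n)
  v[-t] <- solve(lap[-t, -t], b[-t])
  v
}

oracle_cf_closeness <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    r <- sapply(setdiff(seq_len(n), i), function(j)
      oracle_potentials(w, i, j)[i])   # effective resistance i-j
    (n - 1) / sum(r)
  })
}

oracle_cf_betweenness <- function(w) {
  n <- nrow(w)
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    v <- oracle_potentials(w, s, t)
    for (k in seq_len(n)) {
      if (k == s || k == t) next
      bw[k] <- bw[k] + sum(w[k, ] * abs(v[k] - v)) / 2
    }
  }
  bw / ((n - 1) * (n - 2) / 2)
}

oracle_spectral_radius <- function(w, iters = 5000) {
  x <- rep(1, nrow(w))
  for (i in seq_len(iters)) {
    x2 <- w %*% x
    x <- x2 / sqrt(sum(x2^2))
  }
  as.numeric(t(x) %*% w %*% x)
}

oracle_eigenvector <- function(w, iters = 5000) {
  x <- rep(1, nrow(w))
  for (i in seq_len(iters)) {
    x <- w %*% x
    x <- x / sqrt(sum(x^2))
  }
  as.numeric(x / max(x))
}

# Katz via truncated power series sum_k (alpha A)^k 1, unit L2 norm
oracle_katz <- function(w, alpha_frac = 0.9, terms = 20000) {
  n <- nrow(w)
  alpha <- alpha_frac / oracle_spectral_radius(w)
  x <- rep(1, n); term <- rep(1, n)
  for (k in seq_len(terms)) {
    term <- alpha * (w %*% term)
    x <- x + term
    if (max(abs(term)) < 1e-14) break
  }
  as.numeric(x / sqrt(sum(x^2)))
}

oracle_hits_hub <- function(w, iters = 5000) {
  h <- rep(1, nrow(w))
  for (i in seq_len(iters)) {
    a <- t(w) %*% h; a <- a / sqrt(sum(a^2))
    h <- w %*% a;    h <- h / sqrt(sum(h^2))
  }
  as.numeric(h / max(h))
}

oracle_pagerank <- function(w, damping = 0.85, iters = 20000) {
  n <- nrow(w)
  p_trans <- w / rowSums(w)
  x <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    x_new <- damping * as.numeric(t(p_trans) %*% x) + (1 - damping) / n
    if (max(abs(x_new - x)) < 1e-15) { x <- x_new; break }
    x <- x_new
  }
  x
}

# load: for each ordered pair (s, t), one unit of traffic reaches t and is
# traced back toward s, splitting equally among shortest-path predecessors
# at every branch; a node's load is its through-traffic (endpoints
# excluded), summed over ordered pairs.  Per-pair recursion, independent of
# the implementation's batched decreasing-distance sweep.
oracle_load <- function(w, tol = 1e-10) {
  n <- nrow(w)
  d <- oracle_distances(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  load <- numeric(n)
  for (s in seq_len(n)) {
    route_back <- function(v, amount, acc) {
      if (v == s) return(acc)
      preds <- which(abs(d[s, ] + len[, v] - d[s, v]) <=
                       tol * max(1, d[s, v]))
      share <- amount / length(preds)
      for (u in preds) {
        if (u != s) acc[u] <- acc[u] + share
        acc <- route_back(u, share, acc)
      }
      acc
    }
    for (t in seq_len(n)) {
      if (t == s) next
      load <- load + route_back(t, 1, numeric(n))
    }
  }
  load / ((n - 1) * (n - 2))
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (j in nb) for (h in nb) {
      if (j == h) next
      s <- s + (w[i, j] / mx * w[i, h] / mx * w[j, h] / mx)^(1 / 3)
    }
    s / (k * (k - 1))
  })
}

oracle_iterative <- function(w, base_fun) {
  n <- nrow(w)
  out <- numeric(n)
  alive <- seq_len(n)
  while (length(alive)) {
    sub <- w[alive, alive, drop = FALSE]
    sc <- if (length(alive) == 1) 0 else base_fun(sub)
    top <- which(sc >= max(sc) - 1e-9 * max(1, abs(max(sc))))[1]
    out[alive[top]] <- sc[top]
    alive <- alive[-top]
  }
  out
}

oracle_centralities <- function(graph) {
  w <- graph$weights
  cbind(weighted_degree = oracle_weighted_degree(w),
        closeness = oracle_closeness(w),
        currentflow_closeness = oracle_cf_closeness(w),
        currentflow_betweenness = oracle_cf_betweenness(w),
        eigenvector = oracle_eigenvector(w),
        katz = oracle_katz(w),
        hits = oracle_hits_hub(w),
        pagerank = oracle_pagerank(w),
        load = oracle_load(w),
        clustering_coef = oracle_clustering(w),
        iterative_weighted_degree =
          oracle_iterative(w, oracle_weighted_degree),
        iterative_clustering_coef = oracle_iterative(w, oracle_clustering))
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_wilcoxon_exact <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  ranks <- rank(vals)
  obs <- sum(ranks[seq_len(n1)])
  combos <- combn(length(vals), n1)
  stats <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- n1 * (length(vals) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# adjusted Rand index between two labelings (direct contingency formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# small helper: standardized centrality features of a synthetic cohort
make_cohort_features <- function(cfg, split_seed = cfg$seed,
                                 sets = "centralities") {
  co <- generate_cohort(cfg)
  y <- outcome_vector(co$outcomes, "event")
  sp <- stratified_split(y, seed = split_seed)
  scr <- screen_features(co$expression, co$outcomes, "event", sp$train_ids)
  topo <- extract_topology(scr$expression, dataset_tag = "syn", sets = sets)
  feats <- standardize(assemble_features(topo$blocks,
                                         if (length(sets) > 1) "both"
                                         else sets),
                       fit_ids = sp$train_ids)
  list(y = y, split = sp, features = feats, graph = topo$graph)
}

two_clique_graph <- function(n_per = 10, within = 0.9, between = 1e-6) {
  n <- 2 * n_per
  w <- matrix(between, n, n)
  w[seq_len(n_per), seq_len(n_per)] <- within
  w[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- within
  diag(w) <- 0
  patient_graph(w, beta = 1)
}
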