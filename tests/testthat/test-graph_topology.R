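test_that("centrality matrix has exactly 12 canonical columns", {
  g <- random_weighted_graph(15, seed = 1)
  cm <- compute_centralities(g)
  expect_equal(ncol(cm$values), 12L)
  expect_identical(colnames(cm$values),
                   c("weighted_degree", "closeness", "currentflow_closeness",
                     "currentflow_betweenness", "eigenvector", "katz",
                     "hits", "pagerank", "load", "clustering_coef",
                     "iterative_weighted_degree",
                     "iterative_clustering_coef"))
  expect_true(all(is.finite(cm$values)))
})

test_that("symmetric graphs give the symmetric closed-form values", {
  # unweighted triangle: clustering 1, pagerank 1/3 everywhere
  w <- matrix(1, 3, 3); diag(w) <- 0
  cm <- compute_centralities(patient_graph(w))$values
  expect_equal(unname(cm[, "clustering_coef"]), rep(1, 3))
  expect_equal(unname(cm[, "pagerank"]), rep(1 / 3, 3), tolerance = 1e-10)

  # 4-node weighted star: the hub dominates
  ws <- matrix(1e-6, 4, 4)
  ws[1, 2:4] <- ws[2:4, 1] <- c(0.9, 0.8, 0.7)
  diag(ws) <- 0
  cs <- compute_centralities(patient_graph(ws))$values
  for (m in c("weighted_degree", "closeness", "currentflow_betweenness"))
    expect_equal(unname(which.max(cs[, m])), 1L, info = m)
})

test_that("all 12 centralities match the brute-force oracle", {
  for (i in 1:30) {
    g <- random_weighted_graph(3 + (i %% 4), seed = 2000 + i)
    imp <- compute_centralities(g)$values
    ora <- oracle_centralities(g)
    expect_lt(max(abs(imp - ora)), 1e-8)
  }
})

test_that("iterative peeling follows the removal-time rule", {
  # complete equal-weight graph: scores (n-1-t)*w in removal order
  n <- 5; w0 <- 0.4
  w <- matrix(w0, n, n); diag(w) <- 0
  it <- iterative_centrality(patient_graph(w), "weighted_degree")
  expect_equal(unname(it), (n - 1:n) * w0)
  expect_true(all(diff(it) < 0))

  # 3-node path with equal weights: middle node removed first at 2w
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- wp[2, 3] <- wp[3, 2] <- 0.5
  wp[1, 3] <- wp[3, 1] <- 1e-12       # epsilon edge keeps full connectivity
  itp <- iterative_centrality(patient_graph(wp), "weighted_degree")
  expect_equal(unname(which.max(itp)), 2L)
  expect_equal(unname(itp[2]), 1.0, tolerance = 1e-9)
  expect_length(iterative_centrality(random_weighted_graph(7, 3),
                                     "clustering_coef"), 7L)
})

test_that("spectral clustering finds planted structure with eigengap k", {
  g2 <- two_clique_graph(10)
  ma <- spectral_modules(g2, k_max = 8, seed = 1)
  expect_equal(ma$k, 2L)
  truth <- rep(0:1, each = 10)
  expect_equal(oracle_ari(ma$labels, truth), 1)
  expect_equal(nrow(ma$objective_trace), 7L)  # k = 2..8

  # planted partition: 3 blocks, strong contrast
  set.seed(31)
  n <- 90; blocks <- rep(1:3, each = 30)
  w <- matrix(0.1, n, n)
  for (b in 1:3) w[blocks == b, blocks == b] <- 0.9
  w <- w * matrix(runif(n * n, 0.9, 1.1), n)  # mild noise
  w <- (w + t(w)) / 2; diag(w) <- 0
  mp <- spectral_modules(patient_graph(pmin(w, 1)), k_max = 10, seed = 2)
  expect_gte(oracle_ari(mp$labels, blocks), 0.9)

  # permuting nodes permutes labels consistently (up to renaming)
  perm <- sample(20)
  gp <- patient_graph(g2$weights[perm, perm],
                      sample_ids = g2$sample_ids[perm])
  map <- spectral_modules(gp, k_max = 8, seed = 1)
  expect_equal(oracle_ari(map$labels, truth[perm]), 1)
})

test_that("blockmodel recovers two cliques and stays small on noise", {
  g2 <- two_clique_graph(10)
  truth <- rep(0:1, each = 10)
  hits <- vapply(1:10, function(s) {
    ma <- sbm_modules(g2, b_max = 6, seed = s, n_restarts = 5)
    ma$k == 2 && oracle_ari(ma$labels, truth) == 1
  }, logical(1))
  expect_gte(sum(hits), 9L)

  # iid-weight graph: no structure, B stays at 1 or 2
  set.seed(77)
  n <- 60
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(choose(n, 2), 0.2, 0.8)
  w <- w + t(w)
  gnull <- patient_graph(w)
  small <- vapply(1:10, function(s)
    sbm_modules(gnull, b_max = 6, seed = s, n_restarts = 3)$k <= 2,
    logical(1))
  expect_gte(sum(small), 8L)

  tr <- sbm_modules(g2, b_max = 5, seed = 1, n_restarts = 3)$objective_trace
  expect_true(all(diff(tr$b) == 1))
  expect_equal(nrow(tr), length(unique(tr$b)))
})

test_that("module indicators one-hot encode the assignment", {
  ma <- structure(list(labels = setNames(c(0L, 1L, 0L), paste0("s", 1:3)),
                       k = 2L, method = "spectral",
                       objective_trace = NULL),
                  class = "module_assignment")
  ind <- module_indicator_features(ma)
  expect_equal(unname(ind), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_true(all(rowSums(ind) == 1))
  expect_equal(unname(colSums(ind)), c(2, 1))  # module sizes
})

test_that("feature assembly concatenates with provenance and checks ids", {
  gA <- random_weighted_graph(20, seed = 4)
  cA <- compute_centralities(gA)
  gB <- random_weighted_graph(20, seed = 5)
  cB <- compute_centralities(gB)
  both <- assemble_features(list(feature_block(cA, "A", "centralities"),
                                 feature_block(cB, "B", "centralities")))
  expect_equal(ncol(both$values), 24L)
  expect_true(all(grepl("^(A|B)\\|centralities\\|", both$feature_names)))

  # one cohort, centralities + two module sets: d = 12 + k1 + k2
  sa <- spectral_modules(gA, k_max = 5, seed = 1)
  sb <- sbm_modules(gA, b_max = 4, seed = 1, n_restarts = 2)
  ind <- cbind(module_indicator_features(sa), module_indicator_features(sb))
  fb <- assemble_features(list(feature_block(cA, "A", "centralities"),
                               feature_block(ind, "A", "modularities")),
                          set_choice = "both")
  expect_equal(ncol(fb$values), 12L + sa$k + sb$k)

  # self-concatenation stays disambiguated by tag
  dup <- assemble_features(list(feature_block(cA, "A", "centralities"),
                                feature_block(cA, "A2", "centralities")))
  expect_equal(anyDuplicated(dup$feature_names), 0L)

  cBad <- compute_centralities(random_weighted_graph(19, seed = 6))
  expect_error(assemble_features(list(feature_block(cA, "A", "centralities"),
                                      feature_block(cBad, "B",
                                                    "centralities"))),
               "sample ids")
})

test_that("standardization is leakage-safe and drops constant columns", {
  set.seed(12)
  vals <- cbind(m1 = rnorm(30), m2 = runif(30), flat = rep(3, 30))
  rownames(vals) <- paste0("s", 1:30)
  tf <- assemble_features(list(feature_block(vals, "A", "centralities")))
  expect_warning(std <- standardize(tf), "zero-variance")
  expect_equal(std$n_dropped, 1L)
  expect_equal(unname(colMeans(std$values)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(std$values, 2, sd)), c(1, 1), tolerance = 1e-10)

  # scaler fitted on half the rows leaves the other half off-center
  fit_ids <- paste0("s", 1:15)
  tf2 <- assemble_features(list(feature_block(vals[, 1:2], "A",
                                              "centralities")))
  std2 <- standardize(tf2, fit_ids = fit_ids)
  expect_equal(unname(colMeans(std2$values[fit_ids, ])), c(0, 0),
               tolerance = 1e-10)
  rest <- setdiff(rownames(vals), fit_ids)
  expect_gt(max(abs(colMeans(std2$values[rest, ]))), 1e-3)
  expect_error(standardize(tf2, fit_ids = character(0)), "empty")
})

test_that("centrality features carry outcome signal on synthetic cohorts", {
  res <- make_cohort_features(cohort_config(effect_size = 1, seed = 19))
  raw <- res$features$values
  pb <- apply(raw, 2, function(v) abs(cor(v, res$y[rownames(raw)])))
  expect_gt(max(pb), 0.3)
})

test_that("centrality dimension is 12 regardless of original feature count", {
  for (p in c(60, 400)) {
    cfg <- cohort_config(n_samples = 50, n_features = p,
                         n_informative = min(20, p), seed = 23)
    co <- generate_cohort(cfg)
    g <- build_psn(co$expression, beta = 2)
    expect_equal(ncol(compute_centralities(g)$values), 12L)
  }
})
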