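test_that("label prevalence is exact and the generator is deterministic", {
  cfg <- cohort_config(n_samples = 100, class_prevalence = 0.2, seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(sum(outcome_vector(co$outcomes, "event")), 20L)
  co2 <- generate_cohort(cfg)
  expect_identical(co$expression$values, co2$expression$values)
  expect_identical(co$outcomes$outcomes, co2$outcomes$outcomes)
  expect_error(cohort_config(n_samples = 10, class_prevalence = 0.05),
               "infeasible")
})

test_that("null generator (effect_size 0) shows no class separation", {
  cfg <- cohort_config(n_samples = 200, n_features = 400, effect_size = 0,
                       seed = 11)
  co <- generate_cohort(cfg)
  y <- outcome_vector(co$outcomes, "event")
  x <- co$expression$values
  diffs <- apply(x, 1, function(v) {
    m1 <- mean(v[y == 1]); m0 <- mean(v[y == 0])
    se <- sqrt(var(v[y == 1]) / sum(y == 1) + var(v[y == 0]) / sum(y == 0))
    abs(m1 - m0) / se
  })
  expect_gte(mean(diffs < 4), 0.95)
})

test_that("block correlation matches the equicorrelation target", {
  cfg <- cohort_config(n_samples = 500, n_features = 200, n_informative = 0,
                       n_blocks = 4, block_rho = 0.6, seed = 5)
  x <- generate_cohort(cfg)$expression$values
  # features 1..50 share block 1
  cors <- cor(t(x[1:50, ]))
  within <- mean(cors[upper.tri(cors)])
  expect_lt(abs(within - 0.6), 0.05)
  across <- cor(as.vector(x[1, ]), as.vector(x[51, ]))  # different blocks
  expect_lt(abs(across), 0.15)
})

test_that("platform distortions preserve the documented correlations", {
  cfg <- cohort_config(n_samples = 60, n_features = 100, seed = 3)
  pa <- generate_platform_pair(cfg, distortion = "affine",
                               view_noise_sd = 0)
  r <- vapply(seq_len(100), function(f)
    cor(pa$view_a$values[f, ], pa$view_b$values[f, ]), numeric(1))
  expect_true(all(abs(r - 1) < 1e-12))

  pm <- generate_platform_pair(cfg, distortion = "rank-monotone",
                               view_noise_sd = 0)
  rs <- vapply(seq_len(100), function(f)
    cor(pm$view_a$values[f, ], pm$view_b$values[f, ], method = "spearman"),
    numeric(1))
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_error(generate_platform_pair(cfg, distortion = "loess"))
})

test_that("the two platform views agree in patient-correlation structure", {
  mads <- vapply(1:5, function(s) {
    pp <- generate_platform_pair(cohort_config(seed = s))
    ga <- build_psn(pp$view_a, beta = 1)
    gb <- build_psn(pp$view_b, beta = 1)
    ra <- 2 * ga$weights - 1   # invert the beta=1 signed transform
    rb <- 2 * gb$weights - 1
    mean(abs(ra - rb)[upper.tri(ra)])
  }, numeric(1))
  expect_true(all(mads < 0.2))
})

test_that("raw informative features support near-perfect linear separation", {
  # sanity ceiling: with effect >= 1 and many informative features a plain
  # linear classifier on raw features must beat 0.9 held-out bACC.  Block
  # equicorrelation bounds the Bayes accuracy (correlated features share
  # one latent factor), so the ceiling is checked at moderate correlation
  # where it provably holds (Mahalanobis distance > 3).
  cfg <- cohort_config(n_samples = 200, n_features = 200,
                       n_informative = 100, block_rho = 0.3,
                       effect_size = 1, seed = 21)
  co <- generate_cohort(cfg)
  y <- outcome_vector(co$outcomes, "event")
  sp <- stratified_split(y, seed = 21)
  x <- t(co$expression$values)
  fit <- glmnet::glmnet(x[sp$train_ids, ], y[sp$train_ids],
                        family = "binomial", alpha = 0, lambda = 1)
  held <- c(sp$eval_ids, sp$valid_ids)
  prob <- predict(fit, x[held, ], type = "response")[, 1]
  # classify at the training prevalence quantile (imbalance-aware cutoff)
  cut <- quantile(prob, 1 - mean(y[sp$train_ids]))
  expect_gt(balanced_accuracy(y[held], as.integer(prob > cut)), 0.9)
})
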