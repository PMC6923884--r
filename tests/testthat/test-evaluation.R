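test_that("balanced accuracy averages the per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # constant majority prediction on imbalanced truth
  expect_equal(balanced_accuracy(c(0, 0, 0, 0, 1), c(0, 0, 0, 0, 0)), 0.5)
  expect_equal(balanced_accuracy(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 1)),
               0.625)
  # invariant to relabeling both vectors
  y <- rbinom(50, 1, 0.3); p <- rbinom(50, 1, 0.5)
  y[1] <- 1; y[2] <- 0
  expect_equal(balanced_accuracy(y, p), balanced_accuracy(1 - y, 1 - p))
  expect_error(balanced_accuracy(rep(1, 4), c(1, 0, 1, 0)), "both classes")
})

test_that("group comparison detects real separation with Tukey CIs", {
  set.seed(15)
  rec <- data.frame(
    config_id = rep(c("low", "high"), each = 30),
    bacc_valid = c(rnorm(30, 0.80, 0.01), rnorm(30, 0.85, 0.01)))
  cmp <- compare_groups(rec)
  expect_lt(cmp$anova_p, 0.01)
  expect_true(all(cmp$pairs$significant))
  expect_lt(abs(abs(cmp$pairs$delta_bacc) - 0.05), 0.01)
  expect_true(cmp$pairs$ci_lower < cmp$pairs$delta_bacc &
                cmp$pairs$delta_bacc < cmp$pairs$ci_upper)

  dup <- data.frame(config_id = rep(c("a", "b"), each = 3),
                    bacc_valid = rep(0.8, 6))
  expect_error(compare_groups(dup), "variance")
})

test_that("best model breaks ties toward simpler architectures, lower seeds", {
  rec <- data.frame(family = "dnn", config_id = 1:3,
                    params = c("[8,4]", "[8,8,8]", "[2]"),
                    complexity = c(14, 27, 3), replicate = 1,
                    seed = c(5, 3, 9),
                    bacc_valid = c(0.87, 0.87, 0.85),
                    feature_set = "centralities")
  expect_equal(best_model(rec)$params, "[8,4]")  # tie -> lower complexity
  rec$bacc_valid <- c(0.83, 0.87, 0.85)
  expect_equal(best_model(rec)$bacc_valid, 0.87)
  # one winner per scope level
  rec$feature_set <- c("centralities", "modularities", "centralities")
  by_set <- best_model(rec, scope = "feature_set")
  expect_equal(nrow(by_set), 2L)
  expect_setequal(by_set$bacc_valid, c(0.85, 0.87))
})

test_that("transfer harness freezes the model and guards feature sets", {
  res <- make_cohort_features(cohort_config(n_samples = 80, n_features = 200,
                                            effect_size = 1.5, seed = 51))
  m <- train_dnn(res$features, res$y, res$split,
                 dnn_spec(c(8L), epochs = 100, seed = 1))
  ext <- make_cohort_features(cohort_config(n_samples = 60,
                                            n_features = 300,
                                            effect_size = 1.5, seed = 52))
  # unstandardized external centralities from the external cohort's own PSN
  ext_cent <- compute_centralities(ext$graph)
  ext_feats <- assemble_features(list(feature_block(ext_cent, "ext",
                                                    "centralities")))
  before <- m$params
  bacc <- external_validate(m, ext_feats, ext$y)
  expect_identical(m$params, before)        # frozen-model contract
  expect_gte(bacc, 0)
  expect_lte(bacc, 1)

  # modularity features refuse to transfer
  sa <- spectral_modules(ext$graph, k_max = 5, seed = 1)
  mod_feats <- assemble_features(list(feature_block(
    module_indicator_features(sa), "ext", "modularities")),
    set_choice = "modularities")
  expect_error(external_validate(m, mod_feats, ext$y), "centralities")

  mixed <- train_dnn(
    standardize(assemble_features(list(feature_block(
      module_indicator_features(sa), "ext", "modularities")),
      "modularities")),
    ext$y, stratified_split(ext$y, seed = 1),
    dnn_spec(c(4L), epochs = 20, seed = 1))
  expect_error(external_validate(mixed, ext_feats, ext$y), "modularity")
})

test_that("transfer to noise labels stays near chance", {
  res <- make_cohort_features(cohort_config(n_samples = 100,
                                            n_features = 200,
                                            effect_size = 1.5, seed = 53))
  m <- train_dnn(res$features, res$y, res$split,
                 dnn_spec(c(8L), epochs = 200, seed = 2))
  ext <- make_cohort_features(cohort_config(n_samples = 100,
                                            n_features = 200,
                                            effect_size = 1.5, seed = 54))
  ext_feats <- assemble_features(list(feature_block(
    compute_centralities(ext$graph), "ext", "centralities")))
  set.seed(3)
  null_baccs <- replicate(10, {
    ynull <- setNames(sample(ext$y), names(ext$y))
    external_validate(m, ext_feats, ynull)
  })
  expect_gte(mean(null_baccs), 0.35)
  expect_lte(mean(null_baccs), 0.65)
})
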