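test_that("stratified split reproduces the canonical 249/125/124 sizes", {
  y <- setNames(rep(c(0L, 1L), c(398, 100)), paste0("s", 1:498))
  sp <- stratified_split(y, seed = 3)
  expect_length(sp$train_ids, 249L)
  expect_length(sp$eval_ids, 125L)
  expect_length(sp$valid_ids, 124L)
  expect_length(intersect(sp$train_ids, sp$eval_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$eval_ids, sp$valid_ids), names(y))

  # per-class proportions within one sample of global prevalence
  prev <- mean(y)
  for (part in list(sp$train_ids, sp$eval_ids, sp$valid_ids))
    expect_lt(abs(sum(y[part]) - length(part) * prev), 1)

  # tiny cohort: largest-remainder sizes (some partitions lack a class)
  y4 <- setNames(c(0L, 1L, 0L, 1L), paste0("t", 1:4))
  expect_warning(sp4 <- stratified_split(y4, seed = 1), "fewer samples")
  expect_equal(vapply(sp4[1:3], length, integer(1)),
               c(train_ids = 2L, eval_ids = 1L, valid_ids = 1L))
  expect_error(suppressWarnings(
    stratified_split(setNames(c(0L, 0L, 0L, 1L), paste0("u", 1:4)))),
    "fewer samples")
})

test_that("splits are deterministic in the seed and vary across seeds", {
  y <- setNames(rbinom(200, 1, 0.25), paste0("s", 1:200))
  s1 <- stratified_split(y, seed = 5)
  s2 <- stratified_split(y, seed = 5)
  expect_identical(s1, s2)
  s3 <- stratified_split(y, seed = 6)
  expect_false(identical(s1$train_ids, s3$train_ids))
})

test_that("class weights are inverse-frequency with mean sample weight 1", {
  expect_equal(unname(class_weights(rep(c(0, 1), 50))), c(1, 1))
  y <- rep(c(0, 1), c(400, 100))
  w <- class_weights(y)
  expect_equal(unname(w["1"] / w["0"]), 4)
  expect_equal(sum(w[as.character(y)]), length(y))  # normalization
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("architecture enumeration matches the combinatorial counts", {
  expect_length(enumerate_architectures(depths = 1), 3L)
  expect_length(enumerate_architectures(), 34L)          # multisets 3+6+10+15
  expect_length(enumerate_architectures(constraint = "all"), 120L)  # 3+9+27+81
  archs <- enumerate_architectures()
  expect_true(all(vapply(archs, function(a) all(diff(a) <= 0), logical(1))))
  expect_equal(anyDuplicated(archs), 0L)
})

test_that("dnn training is deterministic and learns a separable cohort", {
  res <- make_cohort_features(cohort_config(effect_size = 2, seed = 41))
  spec <- dnn_spec(c(8, 4), epochs = 400, seed = 11)
  m1 <- train_dnn(res$features, res$y, res$split, spec)
  m2 <- train_dnn(res$features, res$y, res$split, spec)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  pred <- predict(m1, res$features$values[res$split$valid_ids, ])
  # strong-signal cohorts land well above the permuted-label band; the
  # 12-feature topological bottleneck caps accuracy below the raw-feature
  # ceiling (see the methods vignette)
  expect_gte(balanced_accuracy(res$y[res$split$valid_ids], pred), 0.75)
  expect_equal(nrow(m1$log), 40L)   # one evaluation every 10 epochs
})

test_that("dnn on permuted labels stays near chance", {
  res <- make_cohort_features(cohort_config(effect_size = 2, seed = 43))
  set.seed(1)
  yp <- setNames(sample(res$y), names(res$y))
  spp <- stratified_split(yp, seed = 43)
  baccs <- vapply(1:5, function(s) {
    m <- train_dnn(res$features, yp, spp,
                   dnn_spec(c(8, 4), epochs = 200, seed = s))
    balanced_accuracy(yp[spp$valid_ids],
                      predict(m, res$features$values[spp$valid_ids, ]))
  }, numeric(1))
  # individual replicates fluctuate (10 positives in the validation set);
  # the replicate mean must sit in the chance band
  expect_gte(mean(baccs), 0.35)
  expect_lte(mean(baccs), 0.65)
})

test_that("dnn spec validates the documented grids", {
  expect_error(dnn_spec(c(16, 4)), "widths")
  expect_error(dnn_spec(c(8, 8, 8, 8, 8)), "hidden layers")
  expect_error(dnn_spec(c(8), dropout = 0.5), "dropout")
  expect_error(dnn_spec(c(8), learning_rate = 1), "learning_rate")
  expect_s3_class(dnn_spec(c(8, 8, 8, 2)), "dnn_spec")
})

test_that("svm and rf baselines fit separable toys and honor protocols", {
  set.seed(6)
  n <- 80
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- setNames(as.integer(x[, 1] + x[, 2] > 0), paste0("s", 1:n))
  rownames(x) <- names(y)
  tf <- assemble_features(list(feature_block(x, "toy", "centralities")))
  tf <- standardize(tf)
  sp <- stratified_split(y, seed = 2)
  ms <- train_svm(tf, y, sp, svm_spec("linear", cost = 4))
  pred_train <- predict(ms, tf$values[sp$train_ids, ])
  expect_gte(balanced_accuracy(y[sp$train_ids], pred_train), 0.95)

  b100 <- score_rf <- function(nt, s) {
    m <- train_rf(tf, y, sp, rf_spec(nt, seed = s))
    balanced_accuracy(y[sp$valid_ids], predict(m, tf$values[sp$valid_ids, ]))
  }
  expect_lte(abs(score_rf(100, 1) - score_rf(10000, 1)), 0.05)
  expect_length(svm_param_grid(), 9L)
  expect_error(rf_spec(50), "n_trees")
})

test_that("grid search enumerates configs x replicates reproducibly", {
  res <- make_cohort_features(cohort_config(n_samples = 80, n_features = 200,
                                            effect_size = 1.5, seed = 47))
  grid <- list(hidden_sizes = list(c(8L), c(4L, 2L)),
               learning_rate = c(1e-3, 5e-3), epochs = 60)
  gs <- grid_search("dnn", res$features, res$y, res$split, grid,
                    replicates = 10, seed = 9)
  expect_equal(nrow(gs$records), 40L)       # 2 archs x 2 lrs x 10 reps
  gs2 <- grid_search("dnn", res$features, res$y, res$split, grid,
                     replicates = 10, seed = 9)
  expect_identical(gs$records, gs2$records)

  # SVM ignores the replicate count: convex problem, one run per point
  gsv <- grid_search("svm", res$features, res$y, res$split,
                     list(cost = svm_param_grid()[4:6]), replicates = 10,
                     seed = 9)
  expect_equal(nrow(gsv$records), 3L)
})
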