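test_that("overall accuracy is the percentage of exact matches", {
  expect_equal(overall_accuracy(1:10, 1:10), 100)
  expect_equal(overall_accuracy(1:4, 5:8), 0)
  expect_equal(overall_accuracy(c(1, 2, 3, 9), c(1, 2, 3, 4)), 75)
  expect_error(overall_accuracy(1:3, 1:4), "equal-length")
})

test_that("per-mode accuracy is undefined (NA), never zero, for absent modes", {
  truth <- c(1, 1, 2, 2)
  pred <- c(1, 5, 2, 2)
  pm <- per_mode_accuracy(pred, truth)
  expect_equal(unname(pm[1]), 50)
  expect_equal(unname(pm[2]), 100)
  expect_true(all(is.na(pm[3:60])))
  # balanced modes: mean of per-mode accuracies equals the overall accuracy
  set.seed(4)
  truth_b <- rep(1:60, each = 10)
  pred_b <- ifelse(runif(600) < 0.8, truth_b, sample(1:60, 600, TRUE))
  pm_b <- per_mode_accuracy(pred_b, truth_b)
  expect_equal(mean(pm_b), overall_accuracy(pred_b, truth_b), tolerance = 1e-12)
})

test_that("confusion matrix is consistent with the accuracies", {
  set.seed(5)
  truth <- rep(1:60, each = 5)
  pred <- ifelse(runif(300) < 0.7, truth, sample(1:60, 300, TRUE))
  cm <- confusion_matrix(pred, truth, normalize = TRUE)
  expect_equal(sum(cm), length(truth))
  expect_equal(unname(rowSums(cm)), rep(5, 60))
  expect_equal(100 * sum(diag(cm)) / sum(cm), overall_accuracy(pred, truth))
  nm <- attr(cm, "normalized")
  expect_equal(unname(diag(nm)),
               unname(per_mode_accuracy(pred, truth)) / 100)
  # perfect prediction -> diagonal
  cmp <- confusion_matrix(truth, truth)
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  expect_error(confusion_matrix(c(0, 1), c(1, 1)), "outside")
})

test_that("factor accuracy projects compound decisions through the ID algebra", {
  # compound-correct implies factor-correct everywhere
  expect_equal(factor_accuracy(1:60, 1:60, "strength"), 100)
  expect_equal(factor_accuracy(1:60, 1:60, "gesture"), 100)
  # truth 27 predicted 7: same pinch/extension, wrong strength (480 vs 0)
  expect_equal(factor_accuracy(7, 27, "gesture"), 100)
  expect_equal(factor_accuracy(7, 27, "wrist"), 100)
  expect_equal(factor_accuracy(7, 27, "strength"), 0)
  expect_equal(factor_accuracy(7, 27, "strength_gesture"), 0)
  # factor accuracy dominates compound accuracy on any input
  set.seed(6)
  truth <- sample(1:60, 500, TRUE)
  pred <- ifelse(runif(500) < 0.5, truth, sample(1:60, 500, TRUE))
  comp <- overall_accuracy(pred, truth)
  for (f in c("strength", "gesture", "wrist", "strength_gesture")) {
    expect_gte(factor_accuracy(pred, truth, f), comp)
  }
  # joint factor accuracy is bounded by each of its margins
  expect_lte(factor_accuracy(pred, truth, "strength_gesture"),
             min(factor_accuracy(pred, truth, "strength"),
                 factor_accuracy(pred, truth, "gesture")))
})

test_that("mean/population-std aggregation reproduces the published summaries", {
  a <- aggregate_mean_popstd(ref_chain_accuracy())
  expect_equal(unname(a["mean"]), 95.30, tolerance = 1e-4)
  expect_equal(unname(a["sd"]), 3.54, tolerance = 1e-3)
  tab <- ref_factor_accuracy()
  s <- aggregate_mean_popstd(tab$strength)
  expect_equal(unname(s["mean"]), 99.347, tolerance = 2e-3)
  expect_equal(unname(s["sd"]), 0.674, tolerance = 2e-3)
  sg <- aggregate_mean_popstd(tab$strength_gesture)
  expect_equal(unname(sg["mean"]), 98.948, tolerance = 2e-3)
  g <- aggregate_mean_popstd(tab$gesture)
  expect_equal(unname(g["mean"]), 99.340, tolerance = 2e-3)
  w <- aggregate_mean_popstd(tab$wrist)
  expect_equal(unname(w["mean"]), 99.045, tolerance = 2e-3)
  # population (divide by N), not sample, std
  expect_equal(unname(aggregate_mean_popstd(c(0, 2))["sd"]), 1)
  expect_equal(unname(aggregate_mean_popstd(rep(7, 5))["sd"]), 0)
})

test_that("evaluate_decoder ties all surfaces together consistently", {
  feats <- small_subject_features()
  sp <- semgdecode:::.split_feature_table(feats, 0.9, shuffle_seed = 1)
  dec <- train_integrated(sp$train, model_spec("knn_fine"))
  rep_ <- evaluate_decoder(dec, sp$test)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$n_test, nrow(sp$test))
  expect_equal(sum(rep_$confusion), rep_$n_test)
  expect_equal(100 * sum(diag(rep_$confusion)) / rep_$n_test,
               rep_$overall_accuracy)
  expect_true(all(rep_$factor_accuracy >= rep_$overall_accuracy - 1e-9))
  expect_true(all(rep_$factor_accuracy >= 0 & rep_$factor_accuracy <= 100))
  expect_true(all(rep_$per_mode_accuracy >= 0 & rep_$per_mode_accuracy <= 100,
                  na.rm = TRUE))
})

test_that("training-proportion sweep keeps chronology and returns full curves", {
  feats <- small_subject_features()
  sw <- training_proportion_sweep(feats, model_spec("knn_fine"),
                                  fractions = c(0.9, 0.5))
  expect_equal(nrow(sw), 2)       # 2 fractions x 1 subject
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 100))
  agg <- attr(sw, "aggregate")
  expect_equal(agg$train_fraction, c(0.9, 0.5))
  # chronology at any fraction: test windows later than train windows
  sp <- semgdecode:::.split_feature_table(feats, 0.5, 3)
  for (id in unique(feats$compound_id)) {
    expect_lt(max(sp$train$trial_position[sp$train$compound_id == id]),
              min(sp$test$trial_position[sp$test$compound_id == id]))
  }
})

test_that("feature-count sweep uses nested subsets of 8k dimensions", {
  feats <- small_subject_features()
  sw <- feature_count_sweep(feats, model_spec("knn_fine"), sizes = c(1, 3, 7))
  expect_equal(sw$dim, c(8, 24, 56))
  agg <- attr(sw, "aggregate")
  expect_equal(agg$n_features, c(1, 3, 7))
  expect_true(all(agg$mean >= 0 & agg$mean <= 100))
})
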