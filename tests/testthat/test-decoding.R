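# toy feature clouds
three_blobs <- function(n = 30, sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n, centers[k, 1], sd), rnorm(n, centers[k, 2], sd))))
  colnames(x) <- c("ch1_MAV", "ch2_MAV")
  list(x = x, y = rep(1:3, each = n))
}

xor_clouds <- function(n = 40, sd = 0.15, seed = 2) {
  set.seed(seed)
  quad <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  x <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n, quad[k, 1], sd), rnorm(n, quad[k, 2], sd))))
  colnames(x) <- c("ch1_MAV", "ch2_MAV")
  list(x = x, y = rep(c(1, 1, 2, 2), each = n))
}

test_that("standardization uses training statistics only", {
  set.seed(3)
  x <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4)
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # test rows are scaled with train statistics, not their own
  xt <- matrix(rnorm(40, mean = 100), 10, 4)
  zt <- apply_standardizer(std, xt)
  expect_gt(min(colMeans(zt)), 10)   # far off-centre under train stats
  # double standardization is guarded
  expect_warning(apply_standardizer(std, z), "already")
  # zero-variance dimension passes through unscaled with a warning
  x0 <- cbind(x, 7)
  expect_warning(s0 <- fit_standardizer(x0), "zero-variance")
  expect_equal(unname(apply_standardizer(s0, x0)[, 5]), rep(0, 50))
})

test_that("linear SVM separates separable blobs; quadratic kernel solves XOR", {
  b <- three_blobs()
  lin <- fit_classifier(b$x, b$y, model_spec("svm_linear"))
  expect_equal(mean(predict(lin, b$x) == b$y), 1)
  xo <- xor_clouds()
  quad <- fit_classifier(xo$x, xo$y, model_spec("svm_quadratic"))
  lin2 <- fit_classifier(xo$x, xo$y, model_spec("svm_linear"))
  expect_equal(mean(predict(quad, xo$x) == xo$y), 1)
  expect_lt(mean(predict(lin2, xo$x) == xo$y), 1)  # linearly inseparable
})

test_that("deterministic families are refit-reproducible; SVM ignores row order", {
  b <- three_blobs(sd = 0.4)
  m1 <- fit_classifier(b$x, b$y, model_spec("svm_quadratic"))
  m2 <- fit_classifier(b$x, b$y, model_spec("svm_quadratic"))
  expect_identical(predict(m1, b$x), predict(m2, b$x))
  set.seed(9)
  perm <- sample(nrow(b$x))
  m3 <- fit_classifier(b$x[perm, ], b$y[perm], model_spec("svm_quadratic"))
  expect_identical(predict(m1, b$x), predict(m3, b$x))
})

test_that("all supported classifier families fit and predict on a toy problem", {
  b <- three_blobs(n = 40, sd = 0.3)
  for (nm in c("tree_fine", "tree_medium", "tree_coarse", "lda", "qda",
               "nb_gaussian", "svm_linear", "svm_quadratic", "svm_cubic",
               "svm_gaussian_fine", "svm_gaussian_medium",
               "svm_gaussian_coarse", "knn_fine", "knn_medium",
               "knn_cosine", "knn_cubic", "knn_weighted", "bagged_trees")) {
    clf <- fit_classifier(b$x, b$y, model_spec(nm), seed = 1)
    acc <- mean(predict(clf, b$x) == b$y)
    expect_gt(acc, 0.9, label = nm)
  }
  # stochastic family is seed-reproducible
  r1 <- fit_classifier(b$x, b$y, model_spec("bagged_trees"), seed = 5)
  r2 <- fit_classifier(b$x, b$y, model_spec("bagged_trees"), seed = 5)
  expect_identical(predict(r1, b$x), predict(r2, b$x))
})

test_that("unsupported and unknown model names are rejected clearly", {
  expect_error(model_spec("nb_kernel"), "no installed backend")
  expect_error(model_spec("rusboosted_trees"), "no installed backend")
  expect_error(model_spec("svm_quartic"), "unknown model")
})

test_that("1-NN memorizes its training labels", {
  b <- three_blobs(n = 20, sd = 1.5)   # heavily overlapping
  knn1 <- fit_classifier(b$x, b$y, model_spec("knn_fine"))
  expect_equal(mean(predict(knn1, b$x) == b$y), 1)
})

test_that("KNN variants agree on well-separated data and break ties deterministically", {
  b <- three_blobs(n = 25, sd = 0.05)
  for (nm in c("knn_medium", "knn_cosine", "knn_cubic", "knn_weighted")) {
    clf <- fit_classifier(b$x, b$y, model_spec(nm))
    expect_equal(mean(predict(clf, b$x) == b$y), 1, label = nm)
  }
  # equidistant two-class tie resolves to the lower class index
  xt <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("ch1_MAV", "ch2_MAV")))
  yt <- c(2, 1)
  clf <- fit_classifier(xt, yt, model_spec("knn_medium", k = 2),
                        standardize = FALSE)
  mid <- matrix(c(1, 0), 1, dimnames = list(NULL, c("ch1_MAV", "ch2_MAV")))
  expect_identical(as.character(predict(clf, mid)), "1")
})

test_that("integrated and chain decoders share the compound prediction interface", {
  feats <- small_subject_features()
  sp <- semgdecode:::.split_feature_table(feats, 0.9, shuffle_seed = 1)
  integ <- train_integrated(sp$train, model_spec("knn_fine"))
  chain <- train_chain(sp$train, model_spec("knn_fine"))
  p_i <- predict_compound(integ, sp$test)
  p_c <- predict_compound(chain, sp$test)
  for (p in list(p_i, p_c)) {
    expect_length(p, nrow(sp$test))
    expect_true(all(p >= 1 & p <= 60))
  }
  fac <- attr(p_c, "factors")
  expect_identical(names(fac), c("gesture_idx", "wrist_idx", "strength_idx"))
  # chain composition obeys the ID algebra
  expect_identical(as.integer(compound_id(fac$gesture_idx, fac$wrist_idx,
                                          fac$strength_idx)),
                   as.integer(p_c))
  # chain factor label spaces are 4 / 5 / 3
  expect_length(chain$gesture$classes, 4)
  expect_length(chain$wrist$classes, 5)
  expect_length(chain$strength$classes, 3)
})

test_that("missing compound classes or factor levels abort training", {
  feats <- small_subject_features()
  drop7 <- feats[feats$compound_id != 7, ]
  expect_error(train_integrated(drop7, model_spec("knn_fine")), "7")
  no960 <- feats[feats$strength_g != 960, ]
  expect_error(train_chain(no960, model_spec("knn_fine")), "strength")
})

test_that("prediction validates the feature dimension", {
  b <- three_blobs()
  clf <- fit_classifier(b$x, b$y, model_spec("svm_linear"))
  expect_error(predict(clf, b$x[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("chain theoretical accuracy is the product rule with scale guards", {
  expect_equal(chain_theoretical_accuracy(1, 1, 1), 1)
  expect_equal(chain_theoretical_accuracy(0.5, 1, 0), 0)
  # product of the published best per-factor accuracies (percent scale)
  expect_equal(chain_theoretical_accuracy(98.98, 98.57, 97.65),
               98.98 * 98.57 * 97.65 / 1e4)
  expect_equal(chain_theoretical_accuracy(0.9898, 0.9857, 0.9765),
               0.9527182, tolerance = 1e-6)
  expect_error(chain_theoretical_accuracy(0.9, 95, 0.9), "mixed scales")
  expect_error(chain_theoretical_accuracy(101, 95, 99), "not valid")
})

test_that("decoders round-trip through the single-file container", {
  b <- three_blobs()
  feats <- small_subject_features()
  sp <- semgdecode:::.split_feature_table(feats, 0.9, shuffle_seed = 1)
  integ <- train_integrated(sp$train, model_spec("knn_fine"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_decoder(integ, path)
  back <- load_decoder(path)
  expect_identical(predict_compound(back, sp$test),
                   predict_compound(integ, sp$test))
})
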