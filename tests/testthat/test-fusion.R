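test_that("metrics follow from the confusion counts", {
  pred <- c(rep("ASD", 9), rep("TD", 1), rep("TD", 8), rep("ASD", 2))
  truth <- c(rep("ASD", 10), rep("TD", 10))
  m <- classification_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  # accuracy identity from class-weighted sensitivity/specificity
  n1 <- sum(truth == "ASD"); n0 <- sum(truth == "TD")
  expect_equal(m$accuracy,
               (m$sensitivity * n1 + m$specificity * n0) / (n1 + n0))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(81)
  truth <- sample(c("ASD", "TD"), 60, replace = TRUE)
  scores <- rnorm(60) + (truth == "ASD")
  got <- roc_auc(scores, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("TD", "ASD")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
  # perfect and inverted scores
  expect_equal(roc_auc(as.numeric(truth == "ASD"), truth), 1)
  expect_equal(roc_auc(-as.numeric(truth == "ASD"), truth), 0)
})

test_that("a separating feature yields perfect cross-validated metrics", {
  set.seed(82)
  labels <- rep(c("ASD", "TD"), each = 20)
  X <- cbind(ifelse(labels == "ASD", 5, 0) + rnorm(40, sd = 0.2))
  m <- evaluate_feature_prefix(X, labels, folds = 4, grid = tiny_grid(),
                               seed = 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_error(evaluate_feature_prefix(X[, 0, drop = FALSE], labels),
               "empty")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(83)
  n <- 200
  labels <- sample(rep(c("ASD", "TD"), each = n / 2))
  X <- matrix(rnorm(n * 20), n, 20)
  m <- evaluate_feature_prefix(X, labels, folds = 4, grid = tiny_grid(),
                               seed = 2)
  expect_gt(m$auc, 0.4)
  expect_lt(m$auc, 0.6)
})

test_that("evaluation is deterministic under a fixed seed", {
  set.seed(84)
  labels <- rep(c("ASD", "TD"), each = 16)
  X <- matrix(rnorm(32 * 5), 32, 5)
  X[, 1] <- X[, 1] + (labels == "ASD")
  m1 <- evaluate_feature_prefix(X, labels, folds = 4,
                                grid = default_rf_grid()[c(2, 6), ],
                                seed = 11)
  m2 <- evaluate_feature_prefix(X, labels, folds = 4,
                                grid = default_rf_grid()[c(2, 6), ],
                                seed = 11)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$accuracy, m2$accuracy)
})

test_that("incremental selection picks the smallest best prefix", {
  set.seed(85)
  labels <- rep(c("ASD", "TD"), each = 20)
  # feature 1 separates perfectly; further features are noise
  X <- cbind(ifelse(labels == "ASD", 5, 0) + rnorm(40, sd = 0.2),
             matrix(rnorm(40 * 4), 40, 4))
  idx <- feature_universe("fMRI")[1:5, ]
  g <- evaluate_local_grid(X, labels, folds = 4, k = 7, seed = 1)
  rk <- rank_features(g, idx)
  scan <- incremental_selection(rk, X, labels, max_prefix = 5,
                                folds = 4, grid = tiny_grid(), seed = 1)
  expect_equal(scan$curve$accuracy[1], 1)
  expect_equal(scan$chosen_length, 1L)   # ties resolve to the shortest
  expect_true(all(scan$curve$accuracy <= 1 & scan$curve$accuracy >= 0))
  # single-feature ranking gives a single-point curve
  scan1 <- incremental_selection(rk[1, ], X, labels, max_prefix = 5,
                                 folds = 4, grid = tiny_grid(), seed = 1)
  expect_equal(nrow(scan1$curve), 1L)
  expect_equal(scan1$chosen_length, 1L)
})

test_that("fusion concatenates the chosen prefixes and checks subjects", {
  set.seed(86)
  labels <- rep(c("ASD", "TD"), each = 20)
  ids <- sprintf("S%02d", 1:40)
  Xs <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(ids, NULL))
  Xf <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(ids, NULL))
  Xs[, 1] <- Xs[, 1] + 2 * (labels == "ASD")
  Xf[, 2] <- Xf[, 2] + 2 * (labels == "ASD")
  idx <- feature_universe("fMRI")[1:6, ]
  mk_scan <- function(X, L) {
    g <- evaluate_local_grid(X, labels, folds = 4, k = 7, seed = 1)
    list(ranked = rank_features(g, idx), chosen_length = L)
  }
  fus <- fuse_modalities(mk_scan(Xs, 3), mk_scan(Xf, 2), Xs, Xf, labels,
                         folds = 4, grid = tiny_grid(), seed = 1)
  expect_equal(fus$fused_length, 5L)
  expect_equal(nrow(fus$smri_prefix), 3L)
  expect_equal(nrow(fus$fmri_prefix), 2L)
  expect_true(fus$metrics$accuracy >= 0 && fus$metrics$accuracy <= 1)

  # empty prefix is refused
  expect_error(
    fuse_modalities(mk_scan(Xs, 0), mk_scan(Xf, 2), Xs, Xf, labels),
    "empty")
  # mismatched subject sets are refused with the subjects named
  Xf2 <- Xf; rownames(Xf2)[1] <- "ZZZ"
  expect_error(
    fuse_modalities(mk_scan(Xs, 1), mk_scan(Xf, 1), Xs, Xf2, labels),
    "ZZZ")
})

test_that("all four classifier families run on separable data", {
  set.seed(87)
  labels <- rep(c("ASD", "TD"), each = 24)
  X <- matrix(rnorm(48 * 4), 48, 4)
  X[, 1:2] <- X[, 1:2] + 5 * (labels == "ASD")
  tab <- benchmark_classifiers(X, labels, folds = 4, grid = tiny_grid(),
                               seed = 1)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$classifier, c("random_forest", "svm",
                                    "naive_bayes", "neural_network"))
  expect_true(all(tab$accuracy >= 0.95))
  # deterministic rerun
  tab2 <- benchmark_classifiers(X, labels, folds = 4, grid = tiny_grid(),
                                seed = 1)
  expect_identical(tab, tab2)
})

test_that("duplicating a selected feature barely moves the metrics", {
  set.seed(88)
  labels <- rep(c("ASD", "TD"), each = 30)
  X <- matrix(rnorm(60 * 3), 60, 3)
  X[, 1] <- X[, 1] + 1.5 * (labels == "ASD")
  m1 <- evaluate_feature_prefix(X, labels, folds = 4, grid = tiny_grid(),
                                seed = 3)
  m2 <- evaluate_feature_prefix(cbind(X, X[, 1]), labels, folds = 4,
                                grid = tiny_grid(), seed = 3)
  expect_lt(abs(m1$accuracy - m2$accuracy), 0.05)
})
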