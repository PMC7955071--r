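make_blobs <- function(seed, n_per = 50, sep = 5, sd = 0.5, d = 2) {
  withr::with_seed(seed, {
    y <- event_labels(rep(c("OSA", "CSA", "NB"), each = n_per))
    centers <- rbind(c(-sep, 0), c(sep, 0), c(0, sep))[rep(1:3, each = n_per), ]
    X <- centers + matrix(rnorm(3 * n_per * d, sd = sd), ncol = d)
    list(X = X, y = y)
  })
}

test_that("balanced class weights follow the inverse-frequency formula", {
  expect_equal(unname(make_class_weights(rep(c("OSA", "CSA", "NB"), each = 50))),
               c(1, 1, 1))

  # clinical-scale class sizes: 1229 OSA, 812 CSA, 1418 NB
  lab <- rep(c("OSA", "CSA", "NB"), c(1229, 812, 1418))
  w <- make_class_weights(event_labels(lab))
  expect_gt(w["CSA"], w["OSA"])
  expect_gt(w["OSA"], w["NB"])
  expect_equal(sum(w * c(1229, 812, 1418)), 3459)

  w2 <- make_class_weights(rep(c("A", "B"), c(10, 1)))
  expect_equal(unname(w2), c(11 / 20, 11 / 2))
})

test_that("1-NN predicts its own training set perfectly", {
  dat <- make_blobs(1, n_per = 20)
  spec <- classifier_spec("knn", knn_k = 1)
  pred <- fit_predict(spec, dat$X, dat$y, dat$X)
  expect_equal(as.character(pred), as.character(dat$y))
})

test_that("all three classifiers separate well-spaced Gaussian blobs", {
  tr <- make_blobs(2, n_per = 34)
  te <- make_blobs(3, n_per = 12)
  for (kind in c("knn", "svm", "rf")) {
    pred <- fit_predict(classifier_spec(kind, seed = 2), tr$X, tr$y, te$X)
    expect_equal(as.character(pred), as.character(te$y),
                 label = paste(kind, "predictions"))
  }
})

test_that("zero-variance features degenerate to a single constant prediction", {
  y <- event_labels(rep(c("OSA", "CSA", "NB"), c(30, 10, 20)))
  X <- matrix(1, length(y), 3)
  Xte <- matrix(1, 7, 3)
  for (kind in c("knn", "svm", "rf")) {
    pred <- suppressWarnings(
      fit_predict(classifier_spec(kind, class_weights = "none", seed = 1),
                  X, y, Xte))
    expect_length(unique(as.character(pred)), 1)
  }
  # with no information and no weighting, RF votes the majority class
  pred_rf <- suppressWarnings(
    fit_predict(classifier_spec("rf", class_weights = "none", seed = 1),
                X, y, Xte))
  expect_equal(as.character(pred_rf), rep("OSA", 7))
})

test_that("mismatched train/test columns raise a schema error", {
  dat <- make_blobs(4, n_per = 10)
  expect_error(fit_predict(classifier_spec("knn"), dat$X, dat$y,
                           dat$X[, 1, drop = FALSE]),
               "columns differ")
})

test_that("stratified folds partition the rows evenly within classes", {
  y <- event_labels(rep(c("OSA", "CSA", "NB"), c(53, 31, 46)))
  folds <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_length(folds, 130)
  tab <- table(folds, y)
  for (cl in colnames(tab)) {
    expect_lte(diff(range(tab[, cl])), 1)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(50, 3)), 10),
               "stratification")
})

test_that("cross-validation assigns each sample to exactly one test fold", {
  dat <- make_blobs(5, n_per = 20, sep = 2, sd = 1.5)
  cv <- cross_validate(classifier_spec("knn"), dat$X, dat$y,
                       n_folds = 5, seed = 5)
  seen <- unlist(lapply(cv$per_fold, `[[`, "test_idx"))
  expect_equal(sort(seen), seq_along(dat$y))
  expect_equal(sum(cv$total_confusion), length(dat$y))
  expect_equal(rowSums(cv$mean_confusion), c(OSA = 1, CSA = 1, NB = 1))
})

test_that("identical seeds give identical predictions for every classifier", {
  dat <- make_blobs(6, n_per = 15, sep = 1.5, sd = 1)
  for (kind in c("knn", "svm", "rf")) {
    cv1 <- cross_validate(classifier_spec(kind, seed = 9), dat$X, dat$y,
                          n_folds = 3, seed = 9)
    cv2 <- cross_validate(classifier_spec(kind, seed = 9), dat$X, dat$y,
                          n_folds = 3, seed = 9)
    expect_identical(cv1$predictions, cv2$predictions, label = kind)
    expect_identical(cv1$mean_confusion, cv2$mean_confusion)
  }
})

test_that("random-forest accuracy does not degrade with more trees", {
  fm <- generate_feature_table(n = 240, informative_columns = 1:5,
                               effect_size = 1, seed = 12)
  acc <- vapply(c(5, 85), function(nt) {
    cv <- cross_validate(classifier_spec("rf", rf_n_trees = nt, seed = 12),
                         fm$values, fm$labels, n_folds = 5, seed = 12)
    mean(cv$fold_accuracy)
  }, 0)
  expect_gte(acc[2], acc[1] - 0.02)
})
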