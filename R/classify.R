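#' Stratified fold assignment
#'
#' Deals the indices of each class round-robin into `k` folds after a seeded
#' shuffle, so per-fold class proportions differ from the global ones by at
#' most one sample per class.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffle.
#' @return integer vector of fold ids (1..k), one per observation.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  y <- as.factor(y)
  if (min(table(y)) < k)
    stop("stratification error: smallest class has fewer samples than folds")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Inverse-frequency ("balanced") class weights
#'
#' weight_c = n_total / (n_classes * n_c), so rare classes get weights above
#' 1 and `sum(weight_c * n_c) == n_total`.
#'
#' @param labels class labels (every class must be non-empty).
#' @return named numeric vector of per-class weights, one per level.
#' @export
make_class_weights <- function(labels) {
  labels <- as.factor(labels)
  counts <- table(droplevels(labels))
  if (any(counts == 0)) stop("empty class")
  w <- as.numeric(sum(counts) / (length(counts) * counts))
  stats::setNames(w, names(counts))
}

#' Classifier specification
#'
#' @param kind `"knn"`, `"svm"` or `"rf"`.
#' @param knn_k neighbor count for KNN (default 5, odd to limit 3-class
#'   ties).
#' @param rf_n_trees random-forest size (default 85 trees).
#' @param svm_cost soft-margin penalty C for the RBF-kernel SVM (default 1).
#' @param class_weights `"balanced"` (inverse frequency) or `"none"`.
#' @param seed seed for the randomized classifiers (RF bootstrap/feature
#'   subsampling).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "knn", "svm"), knn_k = 5,
                            rf_n_trees = 85, svm_cost = 1,
                            class_weights = c("balanced", "none"), seed = 1) {
  kind <- match.arg(kind)
  class_weights <- match.arg(class_weights)
  stopifnot(knn_k >= 1, rf_n_trees >= 1, svm_cost > 0)
  structure(list(kind = kind, knn_k = knn_k, rf_n_trees = rf_n_trees,
                 svm_cost = svm_cost, class_weights = class_weights,
                 seed = seed),
            class = "classifier_spec")
}

# KNN with class-weighted neighbor voting: each neighbor's vote counts its
# class weight; ties broken by the smallest aggregate neighbor distance.
knn_predict <- function(X_train, y_train, X_test, k, class_w) {
  y_train <- as.factor(y_train)
  k <- min(k, nrow(X_train))
  pred <- character(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    d2 <- colSums((t(X_train) - X_test[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- tapply(class_w[as.character(y_train[nn])], y_train[nn], sum)
    votes[is.na(votes)] <- -Inf
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      agg <- vapply(top, function(cl)
        sum(sqrt(d2[nn][y_train[nn] == cl])), 0)
      top <- top[which.min(agg)]
    }
    pred[i] <- top
  }
  factor(pred, levels = levels(y_train))
}

#' Fit a classifier and predict test labels
#'
#' Dispatches on `spec$kind`:
#' \describe{
#'   \item{knn}{k-nearest neighbors under the Euclidean distance with
#'     class-weighted voting.}
#'   \item{svm}{RBF-kernel support vector machine, one-vs-one decomposition
#'     of the multi-class problem with majority vote; class weights scale
#'     the misclassification penalty (libsvm via e1071).}
#'   \item{rf}{random forest, by default 85 trees with bootstrap resampling,
#'     per-node feature subsampling and class-weighted impurity (ranger).}
#' }
#'
#' @param spec a [classifier_spec()].
#' @param X_train,X_test numeric matrices with identical columns.
#' @param y_train training labels.
#' @return factor of predicted labels, one per test row.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test) ||
      !identical(colnames(X_train), colnames(X_test)))
    stop("train and test feature columns differ")
  y_train <- droplevels(as.factor(y_train))
  cw <- if (spec$class_weights == "balanced") make_class_weights(y_train)
        else stats::setNames(rep(1, nlevels(y_train)), levels(y_train))
  if (spec$kind == "knn") {
    return(knn_predict(X_train, y_train, X_test, spec$knn_k, cw))
  }
  colnames(X_train) <- colnames(X_test) <- paste0("f", seq_len(ncol(X_train)))
  if (spec$kind == "svm") {
    fit <- e1071::svm(X_train, y_train, kernel = "radial",
                      cost = spec$svm_cost, class.weights = cw, scale = TRUE)
    pred <- stats::predict(fit, X_test)
    return(factor(as.character(pred), levels = levels(y_train)))
  }
  dtr <- data.frame(.y = y_train, X_train, check.names = FALSE)
  fit <- ranger::ranger(.y ~ ., data = dtr, num.trees = spec$rf_n_trees,
                        class.weights = cw[levels(y_train)],
                        seed = spec$seed, num.threads = 1)
  pred <- stats::predict(fit, data.frame(X_test, check.names = FALSE),
                         num.threads = 1)$predictions
  factor(as.character(pred), levels = levels(y_train))
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits the rows into `n_folds` stratified folds, trains on each
#' complement and predicts the held-out fold. Reports per-fold predictions
#' and confusion matrices, the element-wise mean of the row-normalized
#' per-fold matrices (the "average confusion matrix", in proportions), the
#' summed raw-count matrix, and per-fold accuracies.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix.
#' @param y labels.
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param select_fn optional function `(X_train, y_train) -> column indices`
#'   run inside each training fold (e.g. NCA selection) so feature selection
#'   never sees held-out rows.
#' @return list of class `cv_result`.
#' @export
cross_validate <- function(spec, X, y, n_folds = 10, seed = 1,
                           select_fn = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  folds <- stratified_folds(y, n_folds, seed)
  lv <- levels(y)
  per_fold <- vector("list", n_folds)
  preds <- factor(rep(lv[1], length(y)), levels = lv)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    cols <- seq_len(ncol(X))
    if (!is.null(select_fn))
      cols <- select_fn(X[!te, , drop = FALSE], y[!te])
    p <- fit_predict(spec, X[!te, cols, drop = FALSE], y[!te],
                     X[te, cols, drop = FALSE])
    preds[te] <- as.character(p)
    per_fold[[f]] <- list(
      test_idx = which(te),
      confusion = confusion_matrix(y[te], p, levels = lv),
      selected = cols)
  }
  cms <- lapply(per_fold, `[[`, "confusion")
  norm <- lapply(cms, function(m) {
    rs <- rowSums(m); rs[rs == 0] <- 1
    m / rs
  })
  structure(list(
    spec = spec, n_folds = n_folds, seed = seed,
    folds = folds, predictions = preds,
    per_fold = per_fold,
    mean_confusion = Reduce(`+`, norm) / n_folds,
    total_confusion = Reduce(`+`, cms),
    fold_accuracy = vapply(cms, function(m) sum(diag(m)) / sum(m), 0)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold CV, mean accuracy %.4f\n",
              x$spec$kind, x$n_folds, mean(x$fold_accuracy)))
  cat("average confusion matrix (row proportions):\n")
  print(round(x$mean_confusion, 4))
  invisible(x)
}
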