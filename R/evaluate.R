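#' Confusion matrix
#'
#' counts\[i, j\] = number of samples with true class i predicted as class
#' j, over a fixed class order (default OSA, CSA, NB).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param levels class order; defaults to the union of observed labels in
#'   OSA/CSA/NB order when those labels are used, else sorted.
#' @return C x C integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(levels)) {
    obs <- unique(c(as.character(y_true), as.character(y_pred)))
    levels <- if (all(obs %in% EVENT_LEVELS)) intersect(EVENT_LEVELS, obs)
              else sort(obs)
  }
  y_true <- factor(as.character(y_true), levels = levels)
  y_pred <- factor(as.character(y_pred), levels = levels)
  if (anyNA(y_true) || anyNA(y_pred)) stop("labels outside the class alphabet")
  m <- table(true = y_true, predicted = y_pred)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(true = levels, predicted = levels))
}

#' Per-class recall, precision and F1
#'
#' One-vs-rest decomposition of the confusion matrix: for class c,
#' recall = TP/(TP+FN), precision = TP/(TP+FP), and F1 is their harmonic
#' mean. Degenerate 0/0 ratios are reported as 0 with a warning (so folds
#' missing a class do not break aggregation).
#'
#' @param cm square confusion-matrix of counts (rows true, columns
#'   predicted).
#' @return data frame with one row per class (`recall`, `precision`, `f1`)
#'   plus attribute `macro`, the unweighted means.
#' @export
prf_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  res <- data.frame(class = classes, recall = 0, precision = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cm))) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    if (tp + fn == 0 || tp + fp == 0)
      warning("degenerate class '", classes[i],
              "' (never true or never predicted); metrics set to 0")
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    res[i, 2:4] <- c(rec, prec, f1)
  }
  attr(res, "macro") <- c(recall = mean(res$recall),
                          precision = mean(res$precision),
                          f1 = mean(res$f1))
  res
}

#' Cohen's kappa
#'
#' Chance-corrected agreement k = (p_o - p_e) / (1 - p_e), with observed
#' agreement p_o = trace/N and chance agreement p_e = sum_c a_c * b_c / N^2
#' from the row marginals a_c (true counts) and column marginals b_c
#' (predicted counts).
#'
#' @param cm square confusion matrix of counts.
#' @return scalar in \[-1, 1\].
#' @export
kappa_statistic <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e >= 1) stop("chance agreement p_e = 1; kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Build the evaluation report for a cross-validation run
#'
#' Collects the per-fold confusion matrices, the averaged (row-normalized)
#' matrix, overall and per-class accuracy, per-class and macro
#' recall/precision/F1 on the pooled out-of-fold predictions, and Cohen's
#' kappa.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param y true labels used in the run.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(cv, y) {
  stopifnot(inherits(cv, "cv_result"))
  pooled <- confusion_matrix(y, cv$predictions,
                             levels = rownames(cv$total_confusion))
  prf <- prf_metrics(pooled)
  structure(list(
    classifier = cv$spec$kind,
    spec = unclass(cv$spec),
    n_folds = cv$n_folds,
    seed = cv$seed,
    fold_accuracy = cv$fold_accuracy,
    mean_accuracy = mean(cv$fold_accuracy),
    per_class_accuracy = diag(cv$mean_confusion),
    mean_confusion = cv$mean_confusion,
    total_confusion = pooled,
    per_class = prf,
    macro = attr(prf, "macro"),
    kappa = kappa_statistic(pooled)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d-fold CV\n", x$classifier, x$n_folds))
  cat(sprintf("  mean accuracy %.4f  kappa %.4f\n", x$mean_accuracy, x$kappa))
  cat(sprintf("  per-class accuracy: %s\n",
              paste(sprintf("%s %.4f", names(x$per_class_accuracy),
                            x$per_class_accuracy), collapse = "  ")))
  cat(sprintf("  macro recall %.4f  precision %.4f  F1 %.4f\n",
              x$macro["recall"], x$macro["precision"], x$macro["f1"]))
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' Numeric values are serialized at full precision, so a round-trip
#' reproduces every metric bitwise.
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- report
  out$mean_confusion <- as.data.frame(out$mean_confusion)
  out$total_confusion <- as.data.frame(out$total_confusion)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$mean_confusion <- as.matrix(raw$mean_confusion)
  raw$total_confusion <- as.matrix(raw$total_confusion)
  raw$macro <- unlist(raw$macro)
  raw$per_class_accuracy <- unlist(raw$per_class_accuracy)
  # whole numbers parse as integers; restore double storage throughout
  for (f in c("fold_accuracy", "mean_accuracy", "per_class_accuracy",
              "mean_confusion", "kappa", "macro")) {
    storage.mode(raw[[f]]) <- "double"
  }
  structure(raw, class = "evaluation_report")
}
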