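# Neighborhood component analysis feature selection (diagonal / per-feature
# weights). The learned metric is D_w(x_i, x_j) = sum_l w_l^2 |x_il - x_jl|;
# the objective is the expected leave-one-out soft nearest-neighbor accuracy
# penalized by lambda * sum(w^2):
#
#   xi(w) = sum_i p_i - lambda * sum_l w_l^2,
#   p_i   = sum_{j != i, y_j = y_i} p_ij,
#   p_ij  = exp(-D_w(x_i, x_j)) / sum_{k != i} exp(-D_w(x_i, x_k)).
#
# Weights enter squared, so the sign of the optimization variable is
# irrelevant and |w| is reported.

nca_objective_env <- function(X, y) {
  n <- nrow(X); d <- ncol(X)
  dl <- lapply(seq_len(d), function(l) abs(outer(X[, l], X[, l], "-")))
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  cache <- new.env(parent = emptyenv())
  cache$w <- NULL

  compute <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(invisible(NULL))
    D <- matrix(0, n, n)
    for (l in seq_len(d)) D <- D + w[l]^2 * dl[[l]]
    diag(D) <- Inf
    rm <- apply(D, 1, min)                # row shift for exp() stability
    rm[!is.finite(rm)] <- 0
    K <- exp(-(D - rm))                   # diagonal becomes exp(-Inf) = 0
    P <- K / pmax(rowSums(K), .Machine$double.xmin)
    cache$w <- w
    cache$P <- P
    cache$p_i <- rowSums(P * same)
    invisible(NULL)
  }
  list(
    d = d,
    fn = function(w, lambda) {
      compute(w)
      -(sum(cache$p_i) - lambda * sum(w^2))
    },
    gr = function(w, lambda) {
      compute(w)
      Pin <- cache$P * same
      Pout <- cache$P * cache$p_i         # row i scaled by p_i
      g <- vapply(seq_len(d), function(l)
        sum(Pout * dl[[l]]) - sum(Pin * dl[[l]]), 0)
      -(2 * w * g - 2 * lambda * w)
    }
  )
}

#' Learn NCA feature weights
#'
#' Fits diagonal-metric neighborhood component analysis: per-feature weights
#' maximizing the regularized soft leave-one-out nearest-neighbor accuracy
#' (see the package vignette for the objective). Optimization is L-BFGS from
#' the fixed initialization w = 1; the returned weights are the absolute
#' values at the optimum, so they are nonnegative.
#'
#' @param X numeric matrix, observations x features; callers normally
#'   z-score the columns first (see [nca_select()]).
#' @param y class labels, at least two distinct values.
#' @param lambda ridge penalty on the squared weights, >= 0.
#' @param max_iter optimizer iteration cap (default 500).
#' @param tol relative convergence tolerance (default 1e-9).
#' @param w_init initial weight vector (default all ones).
#' @return nonnegative weight vector of length `ncol(X)`.
#' @export
nca_weights <- function(X, y, lambda = 0, max_iter = 500, tol = 1e-9,
                        w_init = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("need at least two classes")
  if (lambda < 0) stop("lambda must be >= 0")
  obj <- nca_objective_env(X, y)
  if (is.null(w_init)) w_init <- rep(1, obj$d)
  fit <- stats::optim(w_init, fn = obj$fn, gr = obj$gr, lambda = lambda,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  if (fit$convergence != 0 && fit$convergence != 52)
    warning("NCA optimizer did not converge (code ", fit$convergence,
            "); returning best iterate")
  abs(fit$par)
}

#' NCA feature-selection configuration
#'
#' @param n_lambda size of the regularization grid (default 16); the grid is
#'   `n_lambda` equally spaced points on \[0, 15 / n_train\].
#' @param inner_folds folds for the inner cross-validation tuning lambda
#'   (default 5).
#' @param tau relative threshold multiplier: features with weight below
#'   `tau * max(w)` are dropped (default 0.02).
#' @param standardize z-score features before fitting (default TRUE), using
#'   training-fold statistics only inside the tuning loop.
#' @param lambda fixed penalty; `NULL` (default) tunes it on the grid.
#' @param seed RNG seed for fold assignment.
#' @param max_iter,tol optimizer controls passed to [nca_weights()].
#' @return list of class `nca_config`.
#' @export
nca_config <- function(n_lambda = 16, inner_folds = 5, tau = 0.02,
                       standardize = TRUE, lambda = NULL, seed = 1,
                       max_iter = 500, tol = 1e-9) {
  stopifnot(tau > 0, n_lambda >= 2, inner_folds >= 2)
  structure(list(n_lambda = n_lambda, inner_folds = inner_folds, tau = tau,
                 standardize = standardize, lambda = lambda, seed = seed,
                 max_iter = max_iter, tol = tol),
            class = "nca_config")
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, stats::sd)
  sig[sig == 0] <- 1
  list(mu = mu, sig = sig)
}
zscore_apply <- function(X, z) sweep(sweep(X, 2, z$mu, "-"), 2, z$sig, "/")

# 1-NN prediction in the weighted l1 metric D_w = sum_l w_l^2 |.|
nn1_weighted <- function(w, X_train, y_train, X_test) {
  w2 <- w^2
  apply(X_test, 1, function(x) {
    dist <- colSums(w2 * abs(t(X_train) - x))
    y_train[which.min(dist)]
  })
}

#' Tune the NCA regularization penalty
#'
#' Scores each lambda on a grid of `n_lambda` equally spaced points spanning
#' \[0, 15 / n\] by stratified inner cross-validation: NCA weights are fit
#' on each training fold (z-scored with training statistics) and the 0/1
#' loss of a 1-nearest-neighbor rule in the learned weighted metric is
#' measured on the held-out fold. Ties in mean loss go to the larger lambda
#' (the sparser solution).
#'
#' @param X feature matrix (raw scale; standardization is handled per fold).
#' @param y class labels.
#' @param config an [nca_config()].
#' @return list with `best_lambda`, `best_loss`, and `loss_curve` (data
#'   frame of `lambda`, `mean_loss`).
#' @export
tune_lambda <- function(X, y, config = nca_config()) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  grid <- seq(0, 15 / n, length.out = config$n_lambda)
  folds <- stratified_folds(factor(y), config$inner_folds, config$seed)
  losses <- matrix(NA_real_, config$n_lambda, config$inner_folds)
  for (f in seq_len(config$inner_folds)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2 || sum(te) == 0)
      stop("degenerate fold: every fold needs two classes in training")
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (config$standardize) {
      z <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, z); Xte <- zscore_apply(Xte, z)
    }
    w_prev <- NULL
    for (k in seq_along(grid)) {
      w <- nca_weights(Xtr, y[!te], lambda = grid[k],
                       max_iter = config$max_iter, tol = config$tol,
                       w_init = w_prev)
      w_prev <- ifelse(w > 1e-3, w, 1e-3)  # warm start, kept away from 0
      pred <- nn1_weighted(w, Xtr, y[!te], Xte)
      losses[k, f] <- mean(pred != y[te])
    }
  }
  mean_loss <- rowMeans(losses)
  best <- max(which(mean_loss == min(mean_loss)))  # tie -> larger lambda
  list(best_lambda = grid[best], best_loss = mean_loss[best],
       loss_curve = data.frame(lambda = grid, mean_loss = mean_loss))
}

#' Threshold NCA weights into a selected feature set
#'
#' Retains features whose weight reaches the relative threshold
#' T = tau * max(w).
#'
#' @param weights nonnegative weight vector.
#' @param tau relative threshold multiplier (default 0.02).
#' @param columns optional column registry ([feature_columns()]) carried
#'   into the result.
#' @return list of class `nca_selection` with `weights`, `threshold`,
#'   `selected` (indices), and `columns` metadata for the retained set.
#' @export
select_features <- function(weights, tau = 0.02, columns = NULL) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("all weights are zero (lambda too large?)")
  threshold <- tau * max(weights)
  selected <- which(weights >= threshold)
  structure(list(weights = weights, threshold = threshold,
                 selected = selected,
                 columns = if (!is.null(columns)) columns[selected, , drop = FALSE]),
            class = "nca_selection")
}

#' Run the full NCA feature-selection stage
#'
#' Standardizes the features, tunes lambda by inner cross-validation (unless
#' `config$lambda` fixes it), fits the final weights on all rows, and
#' thresholds them at T = tau * max(w).
#'
#' @param fm a [feature_matrix], or a plain numeric matrix with `y` given.
#' @param y labels, only when `fm` is a plain matrix.
#' @param config an [nca_config()].
#' @return `nca_selection` with tuning results (`best_lambda`, `best_loss`,
#'   `loss_curve`) attached when tuning ran.
#' @export
nca_select <- function(fm, y = NULL, config = nca_config()) {
  if (inherits(fm, "feature_matrix")) {
    X <- fm$values; y <- as.character(fm$labels); cols <- fm$columns
  } else {
    X <- as.matrix(fm); y <- as.character(y); cols <- NULL
  }
  tuned <- NULL
  lambda <- config$lambda
  if (is.null(lambda)) {
    tuned <- tune_lambda(X, y, config)
    lambda <- tuned$best_lambda
  }
  Xs <- if (config$standardize) zscore_apply(X, zscore_fit(X)) else X
  w <- nca_weights(Xs, y, lambda = lambda,
                   max_iter = config$max_iter, tol = config$tol)
  sel <- select_features(w, config$tau, columns = cols)
  sel$best_lambda <- lambda
  if (!is.null(tuned)) {
    sel$best_loss <- tuned$best_loss
    sel$loss_curve <- tuned$loss_curve
  }
  sel
}

#' @export
print.nca_selection <- function(x, ...) {
  cat(sprintf("<nca_selection> %d of %d features retained (threshold %.4g)\n",
              length(x$selected), length(x$weights), x$threshold))
  if (!is.null(x$best_lambda))
    cat(sprintf("  lambda = %.4g\n", x$best_lambda))
  invisible(x)
}
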