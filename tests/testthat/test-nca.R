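make_two_class <- function(seed, n = 200, d = 5, shift = 3) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[, 1] <- X[, 1] + ifelse(y == "a", -shift, shift)
    list(X = X, y = y)
  })
}

test_that("a dominant penalty shrinks all weights toward zero", {
  dat <- make_two_class(1)
  w <- nca_weights(scale(dat$X), dat$y, lambda = 1e6)
  expect_lt(max(w), 0.05)
})

test_that("the informative feature earns the dominant weight", {
  hits <- 0
  for (s in 1:5) {
    dat <- make_two_class(s)
    w <- nca_weights(scale(dat$X), dat$y, lambda = 1 / nrow(dat$X))
    if (which.max(w) == 1 && all(w[-1] < 0.1 * w[1])) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("weights are invariant to joint row permutation", {
  dat <- make_two_class(3, n = 120)
  Xs <- scale(dat$X)
  w1 <- nca_weights(Xs, dat$y, lambda = 0.01)
  perm <- withr::with_seed(8, sample(nrow(Xs)))
  w2 <- nca_weights(Xs[perm, ], dat$y[perm], lambda = 0.01)
  expect_equal(w1, w2, tolerance = 1e-3)
})

test_that("single-class input and invalid penalties are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(nca_weights(X, rep("a", 20), lambda = 0), "two classes")
  expect_error(nca_weights(X, rep(c("a", "b"), 10), lambda = -1), "lambda")
  X[1, 1] <- NA
  expect_error(nca_weights(X, rep(c("a", "b"), 10)), "finite")
})

test_that("the relative threshold retains exactly the features above tau*max", {
  sel <- select_features(c(1.0, 0.5, 0.01), tau = 0.02)
  expect_equal(sel$threshold, 0.02)
  expect_equal(sel$selected, c(1L, 2L))

  sel2 <- select_features(c(2.835, 0.05, 0.06), tau = 0.02)
  expect_equal(sel2$threshold, 0.0567)
  expect_equal(sel2$selected, c(1L, 3L))

  expect_equal(select_features(rep(0.4, 6), tau = 0.02)$selected, 1:6)
  expect_error(select_features(rep(0, 4)), "all weights are zero")
  expect_error(select_features(c(-1, 2)), "nonnegative")
})

test_that("the tuning curve spans the grid and finds zero loss when separable", {
  fm <- generate_feature_table(n = 120, informative_columns = 1:5,
                               effect_size = 3, seed = 2)
  tl <- tune_lambda(fm$values, fm$labels, nca_config(seed = 2))
  expect_equal(nrow(tl$loss_curve), 16)
  expect_equal(tl$loss_curve$lambda[1], 0)
  expect_equal(tl$loss_curve$lambda[16], 15 / 120)
  expect_true(all(tl$loss_curve$mean_loss >= 0 & tl$loss_curve$mean_loss <= 1))
  expect_equal(tl$best_loss, min(tl$loss_curve$mean_loss))
  expect_lt(tl$best_loss, 0.05)
  # ties in loss break toward the larger (sparser) lambda
  mins <- which(tl$loss_curve$mean_loss == tl$best_loss)
  expect_equal(tl$best_lambda, tl$loss_curve$lambda[max(mins)])
})

test_that("standardization makes selection invariant to column rescaling", {
  fm <- generate_feature_table(n = 150, informative_columns = c(2, 5, 9),
                               effect_size = 3, seed = 6)
  cfg <- nca_config(lambda = 1 / 150, seed = 6)
  sel1 <- nca_select(fm, config = cfg)
  fm2 <- fm
  fm2$values[, 4] <- fm2$values[, 4] * 1000
  fm2$values[, 9] <- fm2$values[, 9] * 1000
  sel2 <- nca_select(fm2, config = cfg)
  expect_equal(sel1$selected, sel2$selected)
})

test_that("mean weight shrinks along the regularization path", {
  fm <- generate_feature_table(n = 120, informative_columns = 1:5,
                               effect_size = 2, seed = 4)
  Xs <- scale(fm$values)
  grid <- seq(0, 15 / 120, length.out = 8)
  mw <- vapply(grid, function(l)
    mean(nca_weights(Xs, as.character(fm$labels), lambda = l)), 0)
  expect_true(all(diff(mw) <= 0.02))
  expect_lt(mw[8], mw[1])
})

test_that("nca_select returns a coherent selection object", {
  fm <- generate_feature_table(n = 150, informative_columns = c(1, 8, 15),
                               effect_size = 3, seed = 9)
  sel <- nca_select(fm, config = nca_config(lambda = 1 / 150, seed = 9))
  expect_s3_class(sel, "nca_selection")
  expect_true(all(sel$weights >= 0))
  expect_equal(sel$selected, which(sel$weights >= sel$threshold))
  expect_true(all(c(1, 8, 15) %in% sel$selected))
  expect_equal(sel$columns$index, sel$selected)
})
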