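test_that("sample entropy of a constant series is exactly zero", {
  expect_identical(sample_entropy(rep(5, 100), m = 2), 0)
})

test_that("optimized sample entropy matches the brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      N <- sample(50:300, 1)
      m <- sample(1:3, 1)
      x <- rnorm(N)
      r <- 0.2 * sd(x)
      expect_equal(suppressWarnings(sample_entropy(x, m = m, r = r)),
                   sampen_bruteforce(x, m, r), tolerance = 1e-12)
    }
  })
})

test_that("complexity ordering: noise > periodic > constant", {
  withr::with_seed(7, {
    vals <- t(replicate(20, {
      tt <- seq_len(400)
      per <- sin(2 * pi * tt / 20)
      noise <- rnorm(400, sd = sd(per))
      c(noise = sampen_bruteforce(noise, 2, 0.2 * sd(noise)),
        periodic = sampen_bruteforce(per, 2, 0.2 * sd(per)))
    }))
  })
  expect_gt(mean(vals[, "noise"]), mean(vals[, "periodic"]))
  expect_true(all(vals[, "periodic"] > 0))
})

test_that("sample entropy is amplitude invariant (r tracks the signal scale)", {
  withr::with_seed(9, x <- rnorm(400))
  base <- sample_entropy(x)
  for (a in 2^c(-2, 3, 10)) {
    expect_identical(sample_entropy(a * x), base)
  }
})

test_that("degenerate series with no m+1 matches return the finite bound", {
  # strictly increasing with huge jumps: no template pair within r
  x <- 10^(seq_len(40))
  expect_warning(v <- sample_entropy(x, m = 2, r = 1e-12), "upper bound")
  nt <- length(x) - 2
  expect_equal(v, -log(2 / ((nt - 1) * nt)))
  expect_true(is.finite(v))
  expect_error(sample_entropy(rnorm(3), m = 2), "too short")
})

test_that("population variance follows the 1/N formula", {
  expect_equal(variance_pop(c(2, 4, 6)), 8 / 3)
  expect_identical(variance_pop(rep(3.7, 50)), 0)
  withr::with_seed(3, x <- rnorm(100))
  expect_identical(variance_pop(2 * x), 4 * variance_pop(x))
  # population (1/N), not the sample (1/(N-1)) form
  expect_equal(variance_pop(x), var(x) * 99 / 100)
  expect_error(variance_pop(numeric(0)), "empty")
})

test_that("the default registry enumerates the canonical 20 columns", {
  cols <- feature_columns()
  expect_equal(nrow(cols), 20)
  expect_equal(nrow(unique(cols[, c("feature", "channel", "band")])), 20)
  # layout: variance C3 x 5 bands, variance C4, sampen C3, sampen C4
  expect_equal(cols$feature, rep(c("variance", "sample_entropy"), each = 10))
  expect_equal(cols$channel, rep(rep(c("C3", "C4"), each = 5), 2))
  expect_equal(cols$band, rep(eeg_bands()$name, 4))
})

test_that("extraction yields a finite epochs x 20 matrix with labels carried", {
  es <- generate_epochs(synth_config(n_per_class = 3, epoch_len_s = 10, seed = 2))
  fm <- extract_features(es)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$values), c(9, 20))
  expect_true(all(is.finite(fm$values)))
  expect_identical(as.character(fm$labels), as.character(es$labels))
  # variance and entropy columns are nonnegative
  expect_true(all(fm$values >= 0))
})

test_that("a single-channel configuration yields 10 columns", {
  es <- generate_epochs(synth_config(n_per_class = 2, epoch_len_s = 10, seed = 3))
  one <- epoch_set(es$epochs[, 1, , drop = FALSE], es$labels, es$fs,
                   es$channel_names[1], es$epoch_len_s)
  fm <- extract_features(one)
  expect_equal(ncol(fm$values), 10)
})

test_that("feature matrices round-trip through CSV + sidecar", {
  fm <- generate_feature_table(n = 12, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, path, params = list(m = 2))
  back <- read_features(path)
  expect_identical(as.character(back$labels), as.character(fm$labels))
  expect_equal(back$values, fm$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})
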