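test_that("CSV recordings are read with tolerant channel matching", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.csv")
  tab <- data.frame(a = rnorm(6000), b = rnorm(6000), c = rnorm(6000))
  names(tab) <- c("EEG C3-A2", "c4a1", "EMG")
  write.csv(tab, path, row.names = FALSE)

  rec <- read_recording(path, fs = 100)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(rec$channels, c("C3-A2", "C4-A1"))
  expect_length(rec$samples[[1]], 6000)  # 60 s at 100 Hz
  expect_equal(rec$fs, 100)

  expect_error(read_recording(path, channels = c("C3-A2", "O1-A2")),
               "not found.*O1-A2")
  expect_error(read_recording(file.path(dir, "nope.csv")), "not found")
})

test_that("EDF round-trip preserves channels, rate and signal shape", {
  rec <- make_test_recording(seconds = 10)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$fs, 100)
  # quantized to the 16-bit range spanning each channel
  for (ch in 1:2) {
    rng <- diff(range(rec$samples[[ch]])) + 2
    expect_lt(max(abs(back$samples[[ch]] - rec$samples[[ch]])), rng / 65000)
  }
  # read_recording dispatches on the .edf extension and keeps both channels
  rec2 <- read_recording(path)
  expect_equal(rec2$channels, c("C3-A2", "C4-A1"))
})

test_that("corrupt EDF headers are rejected", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(strrep("x", 400)), path)
  expect_error(read_edf(path), "corrupt EDF header")
})

test_that("segmentation yields floor(total/epoch_len) epochs", {
  rec <- make_test_recording(seconds = 95)
  es <- segment_epochs(rec, epoch_len_s = 30)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$epochs), c(3, 2, 3000))  # trailing 5 s dropped
  expect_equal(as.character(es$labels), rep("NB", 3))

  for (secs in c(31, 60, 89, 150)) {
    rec <- make_test_recording(seconds = secs)
    es <- segment_epochs(rec, 30)
    expect_equal(dim(es$epochs)[1], floor(secs %/% 30))
  }
  expect_error(segment_epochs(make_test_recording(seconds = 10), 30),
               "shorter than one epoch")
})

test_that("epoch labels follow the majority-coverage rule", {
  ann <- data.frame(start_s = c(0, 55), duration_s = c(20, 10),
                    label = c("OSA", "CSA"))
  es <- segment_epochs(make_test_recording(seconds = 90, ann = ann), 30)
  # 20/30 of epoch 1 covered by OSA; CSA covers only 5 s of epoch 2
  expect_equal(as.character(es$labels), c("OSA", "NB", "NB"))

  ann2 <- data.frame(start_s = 25, duration_s = 10, label = "CSA")
  es2 <- segment_epochs(make_test_recording(seconds = 30, ann = ann2), 30)
  expect_equal(as.character(es2$labels), "NB")
})

test_that("epoch sets round-trip through the CSV + sidecar format", {
  es <- generate_epochs(synth_config(n_per_class = 2, epoch_len_s = 5, seed = 4))
  dir <- withr::local_tempdir()
  write_epochs(es, dir)
  back <- read_epochs(dir)
  expect_identical(as.character(back$labels), as.character(es$labels))
  expect_equal(back$fs, es$fs)
  expect_lt(max(abs(back$epochs - es$epochs)) / max(abs(es$epochs)), 1e-12)
})

test_that("labels outside the three-class alphabet are rejected", {
  expect_error(event_labels(c("OSA", "MSA")), "unknown event label")
  arr <- array(0, c(2, 1, 10))
  expect_error(epoch_set(arr, c("OSA", "CSA"), fs = 2, "C3-A2", 6),
               "must equal the number of samples")
})
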