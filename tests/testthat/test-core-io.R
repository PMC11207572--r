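test_that("segment_set validates its invariants", {
  d <- array(0, c(4, 3, 10))
  expect_error(segment_set(d, labels = 0:2, subjects = rep(1, 4),
                           channel_names = c("A", "B", "C"), n_classes = 4),
               "labels/subjects")
  expect_error(segment_set(d, labels = c(0, 1, 2, 4), subjects = rep(1, 4),
                           channel_names = c("A", "B", "C"), n_classes = 4),
               "lie in")
  expect_error(segment_set(d, labels = rep(0, 4), subjects = rep(1, 4),
                           channel_names = c("A", "B", "A"), n_classes = 4),
               "duplicate")
  ds <- segment_set(d, rep(0, 4), rep(1, 4), c("A", "B", "C"), n_classes = 4)
  expect_s3_class(ds, "segment_set")
  expect_equal(dim(ds), c(4L, 3L, 10L))
})

test_that("the default montage has 128 unique labels containing the 54-channel subset", {
  m <- montage_128()
  expect_length(m, 128L)
  expect_false(anyDuplicated(m) > 0)
  expect_length(discriminant_54(), 54L)
  expect_true(all(discriminant_54() %in% m))
  expect_length(stimulus_classes_40(), 40L)
})

test_that("save/load round trip is lossless and byte-deterministic", {
  cfg <- tiny_cfg(per_subject = 10L, n_samples = 40L)
  ds <- generate_dataset(cfg)$dataset
  # storage is float32; quantize first so the round trip is exact
  ds$data[] <- readBin(writeBin(as.numeric(ds$data), raw(), size = 4),
                       numeric(), length(ds$data), size = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_dataset(ds, d1)
  save_dataset(ds, d2)
  expect_identical(readBin(file.path(d1, "subject_01.bin"), raw(), 1e6),
                   readBin(file.path(d2, "subject_01.bin"), raw(), 1e6))
  back <- load_dataset(d1)
  expect_identical(back$data, ds$data)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$subjects, ds$subjects)
  expect_identical(back$channel_names, ds$channel_names)
  # 1 segment x 2 channels x 4 samples -> 32-byte payload
  small <- segment_set(array(1, c(1, 2, 4)), 0L, 1L, c("A", "B"),
                       n_classes = 1L)
  d3 <- withr::local_tempdir()
  save_dataset(small, d3)
  expect_equal(file.info(file.path(d3, "subject_01.bin"))$size, 32)
})

test_that("load_dataset reports I/O and manifest errors", {
  d <- withr::local_tempdir()
  expect_error(load_dataset(d), "manifest")
  cfg <- tiny_cfg(per_subject = 8L, n_samples = 20L)
  ds <- generate_dataset(cfg)$dataset
  save_dataset(ds, d)
  # corrupt one array file: truncate
  f <- file.path(d, "subject_02.bin")
  writeBin(raw(16), f)
  expect_error(load_dataset(d), "mismatch")
  file.remove(f)
  expect_error(load_dataset(d), "missing")
})

test_that("subset_channels reorders, is idempotent and commutes with slicing", {
  cfg <- tiny_cfg(per_subject = 10L, n_samples = 30L)
  ds <- generate_dataset(cfg)$dataset
  expect_equal(subset_channels(ds, ds$channel_names), ds)
  keep <- c("CH5", "CH2", "CH7")
  sub <- subset_channels(ds, keep)
  expect_identical(sub$channel_names, keep)
  expect_equal(sub$data[, 2, ], ds$data[, 2, ])  # CH2 is column 2 of ds
  expect_equal(subset_channels(sub, keep), sub)
  # commutes with segment slicing
  a <- subset_segments(subset_channels(ds, keep), 3:7)
  b <- subset_channels(subset_segments(ds, 3:7), keep)
  expect_equal(a, b)
  expect_error(subset_channels(ds, "XX9"), "XX9")
})
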