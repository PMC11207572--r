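test_that("class templates are deterministic, normalized and distinct", {
  cfg <- tiny_cfg()
  t0a <- make_class_template(0, cfg)
  t0b <- make_class_template(0, cfg)
  expect_identical(t0a, t0b)
  expect_error(make_class_template(cfg$n_classes, cfg), "class_id")
  cors <- sapply(1:4, function(k)
    abs(cor(make_class_template(0, cfg), make_class_template(k, cfg))))
  expect_true(all(cors < 0.9))
  for (k in 0:4) {
    tk <- make_class_template(k, cfg)
    expect_equal(max(abs(tk)), 1)
    expect_equal(mean(tk), 0, tolerance = 1e-12)
  }
})

test_that("generated datasets are reproducible and balanced per subject", {
  cfg <- tiny_cfg()
  r1 <- generate_dataset(cfg)
  r2 <- generate_dataset(cfg)
  expect_identical(r1$dataset$data, r2$dataset$data)
  expect_identical(r1$dataset$labels, r2$dataset$labels)
  for (s in unique(r1$dataset$subjects)) {
    counts <- table(r1$dataset$labels[r1$dataset$subjects == s])
    expect_length(counts, cfg$n_classes)
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_error(synth_ground_truth(tiny_cfg(per_subject = 3L)), "balance")
})

test_that("the default configuration reproduces the study structure", {
  cfg <- synth_config()
  expect_identical(cfg$per_subject_counts,
                   c(1995L, 1985L, 1996L, 1996L, 1996L, 1996L))
  expect_identical(cfg$subject_order, c(4L, 1L, 6L, 3L, 2L, 5L))
  expect_equal(sum(cfg$per_subject_counts), 11964L)
  expect_length(cfg$informative_channels, 54L)
  m <- dataset_manifest(cfg)
  expect_equal(m$n_segments, 11964L)
  expect_equal(sum(m$subjects$n_segments), m$n_segments)
  expect_equal(m$n_classes, 40L)
  expect_length(m$class_names, 40L)
})

test_that("noise-free informative traces equal the mixed class template", {
  cfg <- tiny_cfg(snr_db = 300, line_noise_amp = 0, shared_fraction = 1,
                  per_subject = 10L, n_subjects = 1L)
  r <- generate_dataset(cfg)
  gt <- r$ground_truth
  g <- gt$subject_gains[[1]]
  seg1 <- r$dataset$data[1, 1, ]          # informative channel CH1
  cls <- r$dataset$labels[1] + 1L
  expected <- cfg$evoked_amp_uv * g * gt$templates[cls, ]
  expect_equal(seg1, expected, tolerance = 1e-4)
  # non-informative channels carry (negligible) noise only
  expect_lt(sd(r$dataset$data[1, 8, ]), 1e-4 * sd(seg1))
})

test_that("background noise has decreasing power density across octaves", {
  cfg <- tiny_cfg(n_channels = 4L, n_informative = 1L, per_subject = 30L,
                  n_subjects = 1L, n_samples = 400L, line_noise_amp = 0)
  r <- generate_dataset(cfg)
  x <- r$dataset$data[, 4, ]              # noise-only channel
  ps <- rowMeans(apply(x, 1, function(v) abs(fft(v))^2))
  fs <- cfg$sampling_rate_hz
  freqs <- (seq_along(ps) - 1) * fs / length(ps)
  octaves <- list(c(6, 12), c(12, 24), c(24, 48), c(48, 95))
  dens <- sapply(octaves, function(o)
    mean(ps[freqs >= o[1] & freqs < o[2]]))
  expect_true(all(diff(dens) < 0))
})

test_that("mutual information separates informative from background channels", {
  cfg <- tiny_cfg(shared_fraction = 0.8, snr_db = 5)
  ds <- generate_dataset(cfg)$dataset
  m <- pairwise_mutin_matrix(ds, n_bins = 32)
  inf <- 1:3; noise <- 4:8
  mi_inf <- mean(m[inf, inf][upper.tri(matrix(0, 3, 3))])
  mi_cross <- mean(m[inf, noise])
  expect_gt(mi_inf, mi_cross)
  expect_gt(min(m[1, 2], m[1, 3], m[2, 3]), max(m[inf, noise]))
})

test_that("artifact injection honors its rate and registry contract", {
  cfg0 <- tiny_cfg(artifact_rate = 0)
  ds <- generate_dataset(cfg0)$dataset
  r0 <- inject_artifacts(ds, cfg0)
  expect_identical(r0$dataset$data, ds$data)
  expect_equal(nrow(r0$registry), 0)
  cfg1 <- tiny_cfg(artifact_rate = 1)
  r1 <- inject_artifacts(ds, cfg1)
  expect_setequal(unique(r1$registry$segment), seq_len(dim(ds)[1]))
  expect_true(all(r1$registry$length >= 20))
  # bad channels become near-flat
  cfgb <- tiny_cfg(bad_channel_list = "CH6")
  rb <- generate_dataset(cfgb)
  expect_lt(sd(rb$dataset$data[, 6, ]), 1e-3)
})

test_that("pooled channel samples match direct generation", {
  cfg <- tiny_cfg(per_subject = 12L, n_samples = 50L)
  gt <- synth_ground_truth(cfg)
  pm <- pool_channel_samples(cfg, max_segments = 24L, gt = gt)
  expect_equal(ncol(pm), cfg$n_channels)
  expect_equal(nrow(pm), 24L * 50L)
  full <- generate_dataset(cfg)$dataset
  # first subject's first segment occupies the first 50 pooled rows
  expect_equal(pm[1:50, 3], full$data[1, 3, ])
})
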