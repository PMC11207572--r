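test_that("bad channels are detected via the generator ground truth and repaired", {
  cfg <- tiny_cfg(bad_channel_list = "CH6")
  r <- generate_dataset(cfg)
  out <- detect_and_repair_bad_channels(r$dataset)
  expect_identical(out$bad_channels, "CH6")
  # repaired channel is no longer near-flat
  expect_gt(sd(out$dataset$data[, 6, ]), 0.1)
  # clean data: nothing flagged, nothing changed
  clean <- generate_dataset(tiny_cfg())$dataset
  out2 <- detect_and_repair_bad_channels(clean)
  expect_length(out2$bad_channels, 0)
  expect_identical(out2$dataset$data, clean$data)
  expect_error(detect_and_repair_bad_channels(
    subset_channels(clean, c("CH1", "CH2"))), "3 channels")
})

test_that("span rejection catches injected artifacts and only those", {
  cfg0 <- tiny_cfg(artifact_rate = 0)
  clean <- generate_dataset(cfg0)$dataset
  r0 <- reject_spans(clean, z_threshold = 8)
  expect_length(r0$rejected, 0)
  r_inf <- reject_spans(clean, z_threshold = Inf)
  expect_identical(r_inf$dataset$data, clean$data)
  cfg1 <- tiny_cfg(artifact_rate = 0.3)
  inj <- inject_artifacts(clean, cfg1)
  r1 <- reject_spans(inj$dataset, z_threshold = 6)
  expect_setequal(r1$rejected, unique(inj$registry$segment))
})

test_that("scaler statistics follow the pooled mean / unbiased variance formulas", {
  # one channel, values 1,3,5,7 over 2 epochs x 2 samples
  ep <- structure(list(
    data = array(c(1, 5, 3, 7), c(2, 1, 2)),
    labels = c(0L, 1L), subjects = c(1L, 1L),
    channel_names = "A", n_classes = 2L, window = c(0, 2)),
    class = "epoch_array")
  s <- fit_scaler(ep)
  expect_equal(s$mean, 4)
  expect_equal(s$var, 20 / 3)
  expect_equal(s$n, 4)
  scaled <- apply_scaler(ep, s)
  expect_equal(sort(as.numeric(scaled$data)),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  # permutation invariance over epochs
  ep2 <- ep; ep2$data <- ep$data[2:1, , , drop = FALSE]
  expect_equal(fit_scaler(ep2)$mean, s$mean)
  expect_equal(fit_scaler(ep2)$var, s$var)
  # degenerate channel
  epz <- ep; epz$data[] <- 0
  expect_error(fit_scaler(epz), "degenerate")
})

test_that("fit-then-apply standardizes exactly and is idempotent", {
  cfg <- tiny_cfg(per_subject = 20L, n_samples = 60L)
  ds <- generate_dataset(cfg)$dataset
  ep <- make_epochs(ds)
  sc <- fit_scaler(ep)
  z <- apply_scaler(ep, sc)
  pooled <- matrix(aperm(z$data, c(3, 1, 2)), ncol = dim(z$data)[2])
  expect_equal(colMeans(pooled), rep(0, ncol(pooled)), tolerance = 1e-9)
  expect_equal(apply(pooled, 2, var), rep(1, ncol(pooled)),
               tolerance = 1e-6)
  # refitting on standardized data and applying again changes nothing
  z2 <- apply_scaler(z, fit_scaler(z))
  expect_equal(z2$data, z$data, tolerance = 1e-9)
  expect_identical(z$labels, ep$labels)
})

test_that("epoch windows are half-open millisecond slices", {
  cfg <- tiny_cfg(per_subject = 10L, n_samples = 440L)
  ds <- generate_dataset(cfg)$dataset
  full <- make_epochs(ds, c(0, 440))
  expect_equal(full$data, ds$data)
  late <- make_epochs(ds, "360:440")
  expect_equal(dim(late$data)[3], 80L)
  expect_equal(late$data[1, 1, 1], ds$data[1, 1, 361])
  w <- make_epochs(ds, "20:240")
  expect_equal(dim(w$data)[3], 220L)
  expect_error(make_epochs(ds, c(-10, 100)), "window")
  expect_error(make_epochs(ds, c(100, 500)), "window")
})

test_that("evoked averaging is the per-class mean and is linear", {
  cfg <- tiny_cfg(per_subject = 20L, n_samples = 50L, snr_db = 300,
                  line_noise_amp = 0, shared_fraction = 1, n_subjects = 1L)
  r <- generate_dataset(cfg)
  ep <- make_epochs(r$dataset)
  ev <- average_evoked(ep)
  g <- r$ground_truth$subject_gains[[1]]
  for (k in seq_len(cfg$n_classes))
    expect_equal(ev[k, 1, ], cfg$evoked_amp_uv * g *
                   r$ground_truth$templates[k, ], tolerance = 1e-4)
  # single epoch per class: evoked equals that epoch
  one <- ep; keep <- match(unique(ep$labels), ep$labels)
  one$data <- ep$data[keep, , , drop = FALSE]; one$labels <- ep$labels[keep]
  ev1 <- average_evoked(one)
  for (k in seq_len(cfg$n_classes))
    expect_equal(ev1[k, , ], one$data[which(one$labels == k - 1L), , ])
  # missing class
  bad <- ep; bad$data <- ep$data[ep$labels != 0, , , drop = FALSE]
  bad$labels <- ep$labels[ep$labels != 0]
  expect_error(average_evoked(bad), "missing class")
})
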