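test_that("the cyclical learning rate traces a triangular wave", {
  cfg <- train_config(clr_low = 1e-7, clr_high = 1e-3)
  s <- 24
  expect_equal(clr_schedule(0, cfg, s), 1e-7)
  expect_equal(clr_schedule(s, cfg, s), 1e-3)
  expect_equal(clr_schedule(2 * s, cfg, s), 1e-7)
  expect_equal(clr_schedule(s / 2, cfg, s), 1e-7 + (1e-3 - 1e-7) / 2)
  # periodic
  expect_equal(clr_schedule(5, cfg, s), clr_schedule(5 + 2 * s, cfg, s))
  expect_error(train_config(clr_low = 1e-3, clr_high = 1e-7), "clr_low")
})

test_that("k-fold splits partition the data with balanced sizes", {
  sp <- kfold_split(10, 10, seed = 1)
  expect_length(sp, 10)
  expect_true(all(sapply(sp, function(s) length(s$test)) == 1))
  sp2 <- kfold_split(11964, 10, seed = 1)
  sizes <- sort(sapply(sp2, function(s) length(s$test)), decreasing = TRUE)
  expect_equal(sizes, c(rep(1197, 4), rep(1196, 6)))
  for (s in sp2) expect_equal(length(s$train), 11964 - length(s$test))
  all_test <- sort(unlist(lapply(sp2, `[[`, "test")))
  expect_equal(all_test, 1:11964)
  expect_error(kfold_split(5, 10), "n >= k")
  # stratified folds keep class balance within 1
  labs <- rep(0:3, each = 25)
  sps <- kfold_split(100, 5, seed = 2, labels = labs)
  for (s in sps) {
    tab <- table(labs[s$test])
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("leave-one-subject-out rounds rotate with true per-subject sizes", {
  subj <- rep(c(4L, 1L, 6L, 3L, 2L, 5L),
              c(1995L, 1985L, 1996L, 1996L, 1996L, 1996L))
  rounds <- losov_split(subj)
  expect_length(rounds, 6)
  expect_equal(sapply(rounds, `[[`, "test_subject"), c(6L, 1L, 2L, 3L, 4L, 5L))
  r4 <- rounds[[which(sapply(rounds, `[[`, "test_subject") == 4L)]]
  expect_length(r4$test, 1995)
  expect_length(r4$train, 9969)
  # exact partition across rounds
  all_test <- sort(unlist(lapply(rounds, `[[`, "test")))
  expect_equal(all_test, seq_along(subj))
  expect_error(losov_split(rep(1L, 10)), "2 distinct")
})

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), 2L)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  perfect <- confusion_matrix(0:3, 0:3, 4L)
  expect_equal(sum(diag(perfect)), 4)
  expect_error(confusion_matrix(0:2, 0:1, 3L), "equal length")
})

test_that("accuracy implements the one-vs-rest and overall readings", {
  cm <- confusion_matrix(rep(0:1, c(3, 3)), c(0L, 0L, 1L, 1L, 1L, 1L), 2L)
  # cm = [[2,1],[0,3]]: label 0 -> TP=2 FN=1 FP=0 TN=3
  expect_equal(accuracy(cm, label = 0L), (2 + 3) / 6 * 100, tolerance = 1e-9)
  expect_equal(round(accuracy(cm, label = 0L), 2), 83.33)
  expect_equal(accuracy(cm), 5 / 6 * 100)
  perfect <- confusion_matrix(0:3, 0:3, 4L)
  for (l in 0:3) expect_equal(accuracy(perfect, l), 100)
  expect_error(accuracy(confusion_matrix(integer(0), integer(0), 2L)),
               "empty")
})

test_that("the evaluation protocol is perfect in the noise-free limit", {
  cfg <- tiny_cfg(n_channels = 4L, n_informative = 2L, n_classes = 4L,
                  per_subject = 40L, n_subjects = 2L, n_samples = 64L,
                  snr_db = 300, line_noise_amp = 0)
  ds <- generate_dataset(cfg)$dataset
  rep <- evaluate_protocol(ds, "eegnet", window = c(0, 64), scheme = "kfold",
                           cfg = train_config(epochs = 25, batch_size = 40,
                                              seed = 2), k = 2)
  expect_equal(rep$mean_accuracy, 100)
  expect_length(rep$fold_accuracy, 2)
  expect_equal(rep$mean_accuracy, mean(rep$fold_accuracy))
})

test_that("scaler statistics never include validation epochs", {
  cfg <- tiny_cfg(n_channels = 4L, n_informative = 2L, n_classes = 4L,
                  per_subject = 24L, n_subjects = 2L, n_samples = 64L)
  ds <- generate_dataset(cfg)$dataset
  rep <- evaluate_protocol(ds, "eegnet", window = c(0, 64), scheme = "kfold",
                           cfg = train_config(epochs = 1, batch_size = 24,
                                              seed = 3), k = 4)
  n <- dim(ds)[1]
  for (i in seq_along(rep$scalers)) {
    n_train <- rep$splits[[i]]$n_train
    # pooled count = train epochs x window samples only
    expect_equal(rep$scalers[[i]]$n, n_train * 64)
  }
  # losov rounds report their test subject
  rep2 <- evaluate_protocol(ds, "eegnet", window = c(0, 64),
                            scheme = "losov",
                            cfg = train_config(epochs = 1, batch_size = 24,
                                               seed = 3))
  expect_length(rep2$fold_accuracy, 2)
  expect_equal(sapply(rep2$splits, `[[`, "test_subject"), c(2L, 1L))
})
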