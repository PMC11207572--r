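test_that("backpropagation matches finite differences for the convolutional family", {
  set.seed(42)
  g <- build_eegnet(chans = 3, samples = 16, n_classes = 3, f1 = 2, d = 2,
                    f2 = 4, kernel_length = 5, sep_kernel = 3, pool1 = 2,
                    pool2 = 2, dropout = 0)
  x <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  expect_lt(gradcheck_worst(g, x, c(0L, 1L, 2L, 0L)), 1e-4)
})

test_that("backpropagation is exact when pooling trims the time axis", {
  set.seed(43)
  # 18 -> 9 (pool 2) -> 2 with remainder 1 trimmed (pool 4)
  g <- build_eegnet(chans = 2, samples = 18, n_classes = 2, f1 = 2, d = 2,
                    f2 = 4, kernel_length = 5, sep_kernel = 3, pool1 = 2,
                    pool2 = 4, dropout = 0)
  x <- array(rnorm(5 * 2 * 18), c(5, 2, 18))
  expect_lt(gradcheck_worst(g, x, c(0L, 1L, 0L, 1L, 1L)), 1e-4)
})

test_that("backpropagation matches finite differences for the recurrent family", {
  set.seed(44)
  g <- build_cnn_lstm(chans = 3, samples = 8, n_classes = 3, dropout = 0)
  x <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  expect_lt(gradcheck_worst(g, x, c(0L, 1L, 2L, 0L)), 1e-4)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(1)
  x <- array(rnorm(40 * 3 * 32), c(40, 3, 32))
  y <- rep(0:1, 20)
  g <- build_eegnet(chans = 3, samples = 32, n_classes = 2, f1 = 2, d = 2,
                    f2 = 4, kernel_length = 5, sep_kernel = 3, pool1 = 2,
                    pool2 = 2)
  cfg <- train_config(epochs = 3, batch_size = 20, seed = 11)
  m1 <- train_model(g, x, y, cfg)
  m2 <- train_model(g, x, y, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params$Wfc, m2$params$Wfc)
})

test_that("both families fit a linearly separable toy problem to 100%", {
  set.seed(2)
  N <- 60; C <- 4; Tn <- 32
  x <- array(rnorm(N * C * Tn, 0, 0.1), c(N, C, Tn))
  y <- rep(0:1, each = N / 2)
  x[y == 1, 2, ] <- x[y == 1, 2, ] + 1
  g <- build_eegnet(chans = C, samples = Tn, n_classes = 2, f1 = 4, d = 2,
                    f2 = 8, kernel_length = 9, sep_kernel = 4, pool1 = 2,
                    pool2 = 2)
  m <- train_model(g, x, y, train_config(epochs = 40, batch_size = 30,
                                         seed = 3))
  acc <- mean(predict_model(m, x)$labels == y)
  expect_equal(acc, 1)
  # smoothed loss decreases
  sm <- stats::filter(m$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  g2 <- build_cnn_lstm(chans = C, samples = Tn, n_classes = 2)
  m2 <- train_model(g2, aperm(x, c(1, 3, 2)), y,
                    train_config(epochs = 25, batch_size = 30, seed = 3))
  expect_equal(mean(predict_model(m2, aperm(x, c(1, 3, 2)))$labels == y), 1)
})

test_that("out-of-range labels and divergence are reported", {
  g <- build_eegnet(chans = 2, samples = 16, n_classes = 2, f1 = 2, d = 2,
                    f2 = 4, kernel_length = 3, sep_kernel = 3, pool1 = 2,
                    pool2 = 2)
  x <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  expect_error(train_model(g, x, c(0L, 1L, 2L, 0L), train_config(epochs = 1)),
               "label out of range")
})

test_that("inference uses running statistics and disables dropout", {
  set.seed(6)
  g <- build_eegnet(chans = 2, samples = 16, n_classes = 2, f1 = 2, d = 2,
                    f2 = 4, kernel_length = 3, sep_kernel = 3, pool1 = 2,
                    pool2 = 2, dropout = 0.5)
  x <- array(rnorm(10 * 2 * 16), c(10, 2, 16))
  m <- train_model(g, x, rep(0:1, 5), train_config(epochs = 2,
                                                   batch_size = 5, seed = 1))
  p1 <- predict_model(m, x)$probs
  p2 <- predict_model(m, x)$probs
  expect_identical(p1, p2)   # no dropout randomness at inference
  expect_equal(rowSums(p1), rep(1, 10))
})
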