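test_that("activation functions follow their definitions", {
  expect_equal(elu(0), 0)
  expect_equal(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1)
  expect_equal(elu(-1, alpha = 2), 2 * (exp(-1) - 1))
  expect_equal(leaky_relu(3), 3)
  expect_equal(leaky_relu(-1), -0.005)
  expect_equal(leaky_relu(0), 0)
  p <- softmax(rep(1, 40))
  expect_equal(p, rep(1 / 40, 40))
  x <- rnorm(10)
  expect_equal(sum(softmax(x)), 1)
  expect_equal(softmax(x + 5), softmax(x))
  expect_equal(sum(softmax(c(1000, 1001))), 1)  # overflow-safe
})

eegnet_expected <- data.frame(
  name = c("Input", "Conv2D", "Batch_normalization_1", "Depthwise_conv2D",
           "Batch_normalization_2", "Activation_1", "Average_pooling2D_1",
           "Dropout_1", "Separable_conv2D", "Batch_normalization_3",
           "Activation_2", "Average_pooling2D_2", "Dropout_2", "Flatten",
           "Dense", "Softmax"),
  params = c(0, 320, 32, 4320, 320, 0, 0, 0, 7680, 320, 0, 0, 0, 0,
             41640, 0),
  shape = c("54,440,1", "54,440,8", "54,440,8", "1,440,80", "1,440,80",
            "1,440,80", "1,110,80", "1,110,80", "1,110,80", "1,110,80",
            "1,110,80", "1,13,80", "1,13,80", "1040", "40", "40"),
  stringsAsFactors = FALSE)

test_that("the default compact convolutional build reproduces every audited row", {
  g <- build_eegnet()
  expect_length(g$layers, nrow(eegnet_expected))
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    expect_identical(l$name, eegnet_expected$name[i])
    expect_equal(l$n_params, eegnet_expected$params[i],
                 info = l$name)
    expect_identical(paste(l$out_shape, collapse = ","),
                     eegnet_expected$shape[i], info = l$name)
  }
  expect_equal(count_parameters(g)$total, 54632)
})

cnn_lstm_expected <- data.frame(
  name = c("Conv1D_layer1", "Dropout_1", "Activation_1", "Max_Pooling",
           "Conv1D_layer2", "Dropout_2", "Activation_2", "LSTM_layer1",
           "Conv1D_layer3", "Dropout_3", "Activation_3", "LSTM_layer2",
           "Dropout_4", "Dense_1", "Activation_4", "Dense_2", "Softmax"),
  params = c(20864, 0, 0, 0, 24640, 0, 0, 33024, 12352, 0, 0, 12416, 0,
             1782, 0, 2200, 0),
  shape = c("440,128", "440,128", "440,128", "220,128", "220,64",
            "220,64", "220,64", "220,64", "220,64", "220,64", "220,64",
            "32", "32", "54", "54", "40", "40"),
  stringsAsFactors = FALSE)

test_that("the default hybrid recurrent build reproduces every audited row", {
  g <- build_cnn_lstm()
  expect_length(g$layers, nrow(cnn_lstm_expected))
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    expect_identical(l$name, cnn_lstm_expected$name[i])
    expect_equal(l$n_params, cnn_lstm_expected$params[i], info = l$name)
    expect_identical(paste(l$out_shape, collapse = ","),
                     cnn_lstm_expected$shape[i], info = l$name)
  }
  expect_equal(count_parameters(g)$total, 107278)
})

test_that("shape chains stay consistent for non-default geometries", {
  g <- build_eegnet(chans = 1, samples = 64, n_classes = 4)
  # 64 -> 16 -> 2; flatten 2*80
  expect_equal(g$layers[[14]]$out_shape, 160L)
  expect_equal(g$layers[[15]]$n_params, 160 * 4 + 4)
  expect_error(build_eegnet(samples = 3), "underflow|pooling")
  g2 <- build_cnn_lstm(chans = 5, samples = 64, n_classes = 3)
  expect_equal(g2$layers[[1]]$n_params, 3 * 5 * 128 + 128)
  expect_equal(g2$layers[[16]]$n_params, 54 * 3 + 3)
})

test_that("model graphs serialize to JSON with countable parameters", {
  g <- build_eegnet()
  js <- jsonlite::fromJSON(model_graph_json(g), simplifyVector = TRUE)
  expect_equal(js$total_parameters, 54632)
  expect_equal(nrow(js$layers), 16)
  expect_equal(sum(js$layers$parameters), 54632)
})
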