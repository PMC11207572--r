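#' Activation functions
#'
#' `elu()` is the exponential linear unit, `x` for `x >= 0` and
#' `alpha * (exp(x) - 1)` otherwise (continuous at 0); `leaky_relu()`
#' passes positive inputs unchanged and scales negative inputs by a
#' small slope; `softmax()` maps a real vector onto the probability
#' simplex with a max-shift for overflow safety.
#'
#' @param x numeric vector (or array).
#' @param alpha saturation scale for `elu` (default 1) / negative slope
#'   for `leaky_relu` (default 0.005).
#' @return Numeric of the same shape; `softmax` sums to 1.
#' @export
elu <- function(x, alpha = 1) ifelse(x >= 0, x, alpha * (exp(x) - 1))

#' @rdname elu
#' @export
leaky_relu <- function(x, alpha = 0.005) ifelse(x < 0, alpha * x, x)

#' @rdname elu
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

layer_spec <- function(name, kind, out_shape, n_params, params = list()) {
  structure(list(name = name, kind = kind,
                 out_shape = as.integer(out_shape),
                 n_params = as.integer(n_params), params = params),
            class = "layer_spec")
}

new_model_graph <- function(layers, input_shape, n_classes, family) {
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), family = family),
            class = "model_graph")
}

#' Build the compact temporal/depthwise/separable convolutional
#' classifier
#'
#' Declares the layer chain of the compact EEG convolutional network:
#' a temporal 2-D convolution (`f1` filters, kernel `1 x
#' kernel_length`, same padding, no bias), batch normalization, a
#' depthwise spatial convolution across the full montage (kernel
#' `chans x 1`, depth multiplier `d`, no bias), batch normalization,
#' ELU, average pooling `1 x pool1`, dropout, a separable convolution
#' (depthwise kernel `1 x sep_kernel` then `f2` pointwise filters, both
#' without bias), batch normalization, ELU, average pooling
#' `1 x pool2`, dropout, flatten, and a dense softmax classifier with
#' bias. Batch-normalization layers account 4 parameters per feature
#' (scale, shift, running mean, running variance).
#'
#' @param chans input channels (default 54).
#' @param samples input time points (default 440).
#' @param n_classes output classes (default 40).
#' @param f1 temporal filters (default 8).
#' @param d depth multiplier = spatial filters per temporal map
#'   (default 10).
#' @param f2 pointwise filters (default 80).
#' @param kernel_length temporal kernel length (default 40).
#' @param sep_kernel separable depthwise kernel length (default 16).
#' @param pool1,pool2 average-pooling widths (defaults 4 and 8).
#' @param dropout dropout rate (default 0.2).
#' @return A `model_graph`.
#' @export
build_eegnet <- function(chans = 54L, samples = 440L, n_classes = 40L,
                         f1 = 8L, d = 10L, f2 = 80L, kernel_length = 40L,
                         sep_kernel = 16L, pool1 = 4L, pool2 = 8L,
                         dropout = 0.2) {
  stopifnot(chans >= 1L, samples >= 1L)
  fd <- f1 * d
  t1 <- samples %/% pool1
  t2 <- t1 %/% pool2
  if (t1 < 1L || t2 < 1L)
    stop("configuration error: ", samples,
         " samples underflow the pooling chain (", pool1, ", ", pool2, ")")
  L <- list(
    layer_spec("Input", "input", c(chans, samples, 1L), 0),
    layer_spec("Conv2D", "temporal-2D-conv", c(chans, samples, f1),
               kernel_length * f1,
               list(filters = f1, kernel = c(1L, kernel_length),
                    padding = "same", bias = FALSE)),
    layer_spec("Batch_normalization_1", "batch-norm", c(chans, samples, f1),
               4L * f1, list(features = f1)),
    layer_spec("Depthwise_conv2D", "depthwise-2D-conv", c(1L, samples, fd),
               chans * f1 * d,
               list(kernel = c(chans, 1L), depth_multiplier = d, bias = FALSE)),
    layer_spec("Batch_normalization_2", "batch-norm", c(1L, samples, fd),
               4L * fd, list(features = fd)),
    layer_spec("Activation_1", "activation", c(1L, samples, fd), 0,
               list(fn = "elu", alpha = 1)),
    layer_spec("Average_pooling2D_1", "pooling-average", c(1L, t1, fd), 0,
               list(pool = c(1L, pool1))),
    layer_spec("Dropout_1", "dropout", c(1L, t1, fd), 0,
               list(rate = dropout)),
    layer_spec("Separable_conv2D", "separable-2D-conv", c(1L, t1, f2),
               fd * sep_kernel + fd * f2,
               list(depth_kernel = c(1L, sep_kernel), filters = f2,
                    bias = FALSE)),
    layer_spec("Batch_normalization_3", "batch-norm", c(1L, t1, f2),
               4L * f2, list(features = f2)),
    layer_spec("Activation_2", "activation", c(1L, t1, f2), 0,
               list(fn = "elu", alpha = 1)),
    layer_spec("Average_pooling2D_2", "pooling-average", c(1L, t2, f2), 0,
               list(pool = c(1L, pool2))),
    layer_spec("Dropout_2", "dropout", c(1L, t2, f2), 0,
               list(rate = dropout)),
    layer_spec("Flatten", "flatten", t2 * f2, 0),
    layer_spec("Dense", "dense", n_classes, t2 * f2 * n_classes + n_classes,
               list(units = n_classes, bias = TRUE)),
    layer_spec("Softmax", "activation", n_classes, 0, list(fn = "softmax")))
  new_model_graph(L, c(chans, samples, 1L), n_classes, "eegnet")
}

# LSTM parameter count: standard gates with bias, no peepholes.
lstm_params <- function(input_dim, units) 4L * ((input_dim + units) * units + units)

#' Build the hybrid convolutional-recurrent classifier
#'
#' Declares the hybrid 1-D CNN + LSTM chain: a 1-D convolution with 128
#' filters (kernel 3, same padding, bias), dropout, leaky ReLU, max
#' pooling 2, a 64-filter convolution, dropout, leaky ReLU, a
#' sequence-returning 64-unit LSTM, a 64-filter convolution, dropout,
#' leaky ReLU, a final-state 32-unit LSTM, dropout, a 54-neuron dense
#' layer with leaky ReLU, and a dense softmax classifier. LSTM layers
#' use standard gates with bias and no peepholes, so a layer with
#' `u` units and `i` inputs carries `4 * ((i + u) * u + u)` parameters.
#'
#' @param chans input channels (default 54).
#' @param samples input time points (default 440).
#' @param n_classes output classes (default 40).
#' @param dropout dropout rate (default 0.2).
#' @param leaky_alpha negative slope of the leaky ReLU (default 0.005).
#' @return A `model_graph`.
#' @export
build_cnn_lstm <- function(chans = 54L, samples = 440L, n_classes = 40L,
                           dropout = 0.2, leaky_alpha = 0.005) {
  stopifnot(chans >= 1L, samples >= 2L)
  tp <- samples %/% 2L
  if (tp < 1L) stop("configuration error: pooling underflow")
  L <- list(
    layer_spec("Conv1D_layer1", "1D-conv", c(samples, 128L),
               3L * chans * 128L + 128L,
               list(filters = 128L, kernel = 3L, padding = "same",
                    bias = TRUE)),
    layer_spec("Dropout_1", "dropout", c(samples, 128L), 0,
               list(rate = dropout)),
    layer_spec("Activation_1", "activation", c(samples, 128L), 0,
               list(fn = "leaky_relu", alpha = leaky_alpha)),
    layer_spec("Max_Pooling", "pooling-max", c(tp, 128L), 0,
               list(pool = 2L)),
    layer_spec("Conv1D_layer2", "1D-conv", c(tp, 64L),
               3L * 128L * 64L + 64L,
               list(filters = 64L, kernel = 3L, padding = "same",
                    bias = TRUE)),
    layer_spec("Dropout_2", "dropout", c(tp, 64L), 0, list(rate = dropout)),
    layer_spec("Activation_2", "activation", c(tp, 64L), 0,
               list(fn = "leaky_relu", alpha = leaky_alpha)),
    layer_spec("LSTM_layer1", "recurrent-memory", c(tp, 64L),
               lstm_params(64L, 64L),
               list(units = 64L, return_sequences = TRUE)),
    layer_spec("Conv1D_layer3", "1D-conv", c(tp, 64L),
               3L * 64L * 64L + 64L,
               list(filters = 64L, kernel = 3L, padding = "same",
                    bias = TRUE)),
    layer_spec("Dropout_3", "dropout", c(tp, 64L), 0, list(rate = dropout)),
    layer_spec("Activation_3", "activation", c(tp, 64L), 0,
               list(fn = "leaky_relu", alpha = leaky_alpha)),
    layer_spec("LSTM_layer2", "recurrent-memory", 32L,
               lstm_params(64L, 32L),
               list(units = 32L, return_sequences = FALSE)),
    layer_spec("Dropout_4", "dropout", 32L, 0, list(rate = dropout)),
    layer_spec("Dense_1", "dense", 54L, 32L * 54L + 54L,
               list(units = 54L, bias = TRUE)),
    layer_spec("Activation_4", "activation", 54L, 0,
               list(fn = "leaky_relu", alpha = leaky_alpha)),
    layer_spec("Dense_2", "dense", n_classes, 54L * n_classes + n_classes,
               list(units = n_classes, bias = TRUE)),
    layer_spec("Softmax", "activation", n_classes, 0, list(fn = "softmax")))
  new_model_graph(L, c(samples, chans), n_classes, "cnn_lstm")
}

#' Per-layer and total trainable parameter counts
#'
#' Counts derive solely from the declared layer hyperparameters;
#' batch-norm layers contribute 4 per feature and convolution/dense
#' layers include a bias term iff their bias flag is set.
#'
#' @param g a `model_graph`.
#' @return A list with `per_layer` (named integer vector) and `total`.
#' @export
count_parameters <- function(g) {
  stopifnot(inherits(g, "model_graph"))
  per <- vapply(g$layers, function(l) l$n_params, integer(1))
  names(per) <- vapply(g$layers, function(l) l$name, character(1))
  list(per_layer = per, total = sum(per))
}

#' @export
print.model_graph <- function(x, ...) {
  cat("<model_graph> family: ", x$family, "\n", sep = "")
  nm <- vapply(x$layers, function(l) l$name, character(1))
  sh <- vapply(x$layers, function(l)
    paste0("(None, ", paste(l$out_shape, collapse = ", "), ")"), character(1))
  pp <- vapply(x$layers, function(l) format(l$n_params, big.mark = ","),
               character(1))
  w1 <- max(nchar(nm)); w2 <- max(nchar(sh))
  cat(sprintf("  %-*s  %-*s  %s\n", w1, "Layer (Type)", w2, "Output Shape",
              "Parameters"))
  for (i in seq_along(nm))
    cat(sprintf("  %-*s  %-*s  %s\n", w1, nm[i], w2, sh[i], pp[i]))
  cat("  Total number of parameters: ",
      format(count_parameters(x)$total, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Serialize a model graph to JSON
#'
#' Writes the declarative layer list (names, kinds, hyperparameters,
#' output shapes and parameter counts) for auditing.
#'
#' @param g a `model_graph`.
#' @param path optional file path; if `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
model_graph_json <- function(g, path = NULL) {
  obj <- list(family = g$family, input_shape = g$input_shape,
              n_classes = g$n_classes,
              layers = lapply(g$layers, function(l)
                list(name = l$name, kind = l$kind,
                     output_shape = l$out_shape, parameters = l$n_params,
                     hyperparameters = l$params)),
              total_parameters = count_parameters(g)$total)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
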