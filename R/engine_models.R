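# Model instantiation, forward/backward passes and the Nadam optimizer.

## ---- 1-D convolution over time (same padding, kernel 3-ish) ----
# X: (N*T) x Cin with row index n + N*(t-1); W: k x Cin x F.

conv1d_fwd <- function(X, N, T, W, b) {
  k <- dim(W)[1L]; Cin <- dim(W)[2L]; F <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  Ap <- array(0, c(N, T + k - 1L, Cin))
  Ap[, pad + seq_len(T), ] <- array(X, c(N, T, Cin))
  Y <- matrix(0, N * T, F)
  for (q in seq_len(k))
    Y <- Y + matrix(Ap[, q:(q + T - 1L), ], N * T, Cin) %*% W[q, , ]
  Y <- Y + rep(b, each = N * T)
  list(out = Y, Ap = Ap)
}

conv1d_bwd <- function(dY, cache, N, T, W, need_dx = TRUE) {
  k <- dim(W)[1L]; Cin <- dim(W)[2L]
  pad <- (k - 1L) %/% 2L
  dW <- array(0, dim(W))
  dAp <- if (need_dx) array(0, dim(cache$Ap))
  for (q in seq_len(k)) {
    Xq <- matrix(cache$Ap[, q:(q + T - 1L), ], N * T, Cin)
    dW[q, , ] <- crossprod(Xq, dY)
    if (need_dx)
      dAp[, q:(q + T - 1L), ] <- dAp[, q:(q + T - 1L), ] +
        array(dY %*% t(W[q, , ]), c(N, T, Cin))
  }
  list(dX = if (need_dx) matrix(dAp[, pad + seq_len(T), ], N * T, Cin),
       dW = dW, db = colSums(dY))
}

## ---- LSTM ----
# X: array (N, T, Fin); W: (Fin + u) x 4u with gate order [i, f, g, o].

sigm <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(X, W, b, return_sequences = TRUE) {
  N <- dim(X)[1L]; T <- dim(X)[2L]
  u <- length(b) %/% 4L
  h <- matrix(0, N, u); cc <- matrix(0, N, u)
  steps <- vector("list", T)
  H <- if (return_sequences) array(0, c(N, T, u))
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], N)
    Z <- cbind(xt, h) %*% W
    Z <- sweep(Z, 2L, b, "+")
    i <- sigm(Z[, 1:u, drop = FALSE])
    f <- sigm(Z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h_prev_step <- h
    h <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                       tc = tc, h_prev = h_prev_step, xt = xt)
    if (return_sequences) H[, t, ] <- h
  }
  list(out = if (return_sequences) H else h, steps = steps, X = X)
}

lstm_bwd <- function(dOut, cache, W, return_sequences = TRUE) {
  X <- cache$X
  N <- dim(X)[1L]; T <- dim(X)[2L]; Fin <- dim(X)[3L]
  u <- (nrow(W) - Fin)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dX <- array(0, dim(X))
  dh_next <- matrix(0, N, u)
  dc_next <- matrix(0, N, u)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dh <- dh_next + if (return_sequences) matrix(dOut[, t, ], N)
      else if (t == T) dOut else matrix(0, N, u)
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    inp <- cbind(st$xt, st$h_prev)
    dW <- dW + crossprod(inp, dZ)
    db <- db + colSums(dZ)
    dinp <- dZ %*% t(W)
    dX[, t, ] <- dinp[, seq_len(Fin), drop = FALSE]
    dh_next <- dinp[, Fin + seq_len(u), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- model instantiation ----

graph_hp <- function(graph) {
  ly <- function(name) Filter(function(l) l$name == name, graph$layers)[[1L]]
  if (graph$family == "eegnet") {
    conv <- ly("Conv2D"); dw <- ly("Depthwise_conv2D")
    sep <- ly("Separable_conv2D")
    p1 <- ly("Average_pooling2D_1"); p2 <- ly("Average_pooling2D_2")
    dr <- ly("Dropout_1")
    list(chans = graph$input_shape[1L], samples = graph$input_shape[2L],
         K = graph$n_classes,
         f1 = conv$params$filters, k1 = conv$params$kernel[2L],
         d = dw$params$depth_multiplier,
         fd = conv$params$filters * dw$params$depth_multiplier,
         f2 = sep$params$filters, ks = sep$params$depth_kernel[2L],
         p1 = p1$params$pool[2L], p2 = p2$params$pool[2L],
         dropout = dr$params$rate)
  } else {
    dr <- ly("Dropout_1"); act <- ly("Activation_1")
    list(chans = graph$input_shape[2L], samples = graph$input_shape[1L],
         K = graph$n_classes, dropout = dr$params$rate,
         alpha = act$params$alpha)
  }
}

#' Instantiate trainable weights for a declared model graph
#'
#' @param graph a `model_graph` from [build_eegnet()] or
#'   [build_cnn_lstm()].
#' @param seed RNG seed for weight initialization.
#' @return A `vep_model`: list with the graph, hyperparameters, a named
#'   parameter list and batch-norm running statistics.
#' @export
instantiate_model <- function(graph, seed = 1L) {
  hp <- graph_hp(graph)
  params <- with_seed(mix_seed(seed, 31), {
    if (graph$family == "eegnet") {
      t2 <- (hp$samples %/% hp$p1) %/% hp$p2
      flat <- t2 * hp$f2
      list(
        Wt = glorot(hp$k1, hp$k1 * hp$f1, c(hp$k1, hp$f1)),
        bn1_gamma = rep(1, hp$f1), bn1_beta = rep(0, hp$f1),
        Wd = glorot(hp$chans, hp$d, c(hp$chans, hp$f1, hp$d)),
        bn2_gamma = rep(1, hp$fd), bn2_beta = rep(0, hp$fd),
        Wsd = glorot(hp$ks, hp$ks, c(hp$ks, hp$fd)),
        Wsp = glorot(hp$fd, hp$f2, c(hp$fd, hp$f2)),
        bn3_gamma = rep(1, hp$f2), bn3_beta = rep(0, hp$f2),
        Wfc = glorot(flat, hp$K, c(flat, hp$K)), bfc = rep(0, hp$K))
    } else {
      b1 <- rep(0, 4L * 64L); b1[65:128] <- 1     # forget-gate bias
      b2 <- rep(0, 4L * 32L); b2[33:64] <- 1
      list(
        W1 = he_uniform(3 * hp$chans, c(3L, hp$chans, 128L)), bc1 = rep(0, 128),
        W2 = he_uniform(3 * 128, c(3L, 128L, 64L)), bc2 = rep(0, 64),
        Wl1 = glorot(64 + 64, 4 * 64, c(128L, 256L)), bl1 = b1,
        W3 = he_uniform(3 * 64, c(3L, 64L, 64L)), bc3 = rep(0, 64),
        Wl2 = glorot(64 + 32, 4 * 32, c(96L, 128L)), bl2 = b2,
        Wd1 = glorot(32, 54, c(32L, 54L)), bd1 = rep(0, 54),
        Wd2 = glorot(54, hp$K, c(54L, hp$K)), bd2 = rep(0, hp$K))
    }
  })
  bn_state <- if (graph$family == "eegnet")
    list(bn1_mean = rep(0, hp$f1), bn1_var = rep(1, hp$f1),
         bn2_mean = rep(0, hp$fd), bn2_var = rep(1, hp$fd),
         bn3_mean = rep(0, hp$f2), bn3_var = rep(1, hp$f2))
  structure(list(graph = graph, hp = hp, params = params,
                 bn_state = bn_state, family = graph$family),
            class = "vep_model")
}

## ---- EEGNet-family forward/backward ----
# x: array (N, C, T). The temporal-conv/batch-norm/depthwise head runs
# as one fused compiled block (its backward pass recomputes the conv
# activations rather than caching them); the separable tail uses the
# per-stage kernels.

eegnet_fwd <- function(model, x, training = TRUE) {
  hp <- model$hp; p <- model$params; bs <- model$bn_state
  N <- dim(x)[1L]; C <- dim(x)[2L]; Tn <- dim(x)[3L]
  stopifnot(C == hp$chans, Tn == hp$samples)
  M0 <- matrix(x, N * C, Tn)                       # rows (n, c)
  bl <- eegnet_block1_fwd(M0, p$Wt, p$bn1_gamma, p$bn1_beta,
                          bs$bn1_mean, bs$bn1_var, p$Wd,
                          N, C, Tn, training, 0.9, 1e-5)
  Z <- bl$out                                      # (N*T) x fd
  T1 <- Tn %/% hp$p1
  b2 <- bnelu_pool_fwd_cpp(Z, p$bn2_gamma, p$bn2_beta,
                           bs$bn2_mean, bs$bn2_var, training, 0.9, 1e-5,
                           N, Tn, hp$p1)           # (N*T1) x fd
  dr1 <- dropout_fwd(b2$out, hp$dropout, training)
  sdo <- sepdw_fwd_cpp(dr1$out, p$Wsd, N, T1)
  pw <- sdo %*% p$Wsp                              # (N*T1) x f2
  T2 <- T1 %/% hp$p2
  b3 <- bnelu_pool_fwd_cpp(pw, p$bn3_gamma, p$bn3_beta,
                           bs$bn3_mean, bs$bn3_var, training, 0.9, 1e-5,
                           N, T1, hp$p2)
  dr2 <- dropout_fwd(b3$out, hp$dropout, training)
  # (N*T2) x f2 and N x (T2*f2) share the same column-major layout
  flat <- matrix(dr2$out, N, T2 * hp$f2)
  logits <- flat %*% p$Wfc + rep(p$bfc, each = N)
  cache <- list(N = N, C = C, Tn = Tn, M0 = M0, bl_mean = bl$mean,
                bl_inv_std = bl$inv_std, Z = Z, b2 = b2, T1 = T1,
                dr1 = dr1, sdo = sdo, pw = pw, b3 = b3, T2 = T2,
                dr2 = dr2, flat = flat)
  list(logits = logits, cache = cache,
       bn_updates = if (training) list(
         bn1_mean = as.numeric(bl$run_mean), bn1_var = as.numeric(bl$run_var),
         bn2_mean = as.numeric(b2$run_mean), bn2_var = as.numeric(b2$run_var),
         bn3_mean = as.numeric(b3$run_mean), bn3_var = as.numeric(b3$run_var)))
}

eegnet_bwd <- function(model, cache, dlogits) {
  hp <- model$hp; p <- model$params
  N <- cache$N; C <- cache$C; Tn <- cache$Tn
  T1 <- cache$T1; T2 <- cache$T2
  g <- list()
  g$bfc <- colSums(dlogits)
  g$Wfc <- crossprod(cache$flat, dlogits)
  dflat <- dlogits %*% t(p$Wfc)
  dpool2 <- matrix(dflat, N * T2, hp$f2)
  dpool2 <- dropout_bwd(dpool2, cache$dr2)
  bb3 <- bnelu_pool_bwd_cpp(cache$pw, dpool2, p$bn3_gamma, p$bn3_beta,
                            cache$b3$mean, cache$b3$inv_std, N, T1, hp$p2)
  g$bn3_gamma <- as.numeric(bb3$dgamma); g$bn3_beta <- as.numeric(bb3$dbeta)
  dpw <- bb3$dX
  g$Wsp <- crossprod(cache$sdo, dpw)
  dsd <- dpw %*% t(p$Wsp)
  sb <- sepdw_bwd_cpp(cache$dr1$out, dsd, p$Wsd, N, T1)
  g$Wsd <- sb$dW
  ddr1 <- dropout_bwd(sb$dX, cache$dr1)
  bb2 <- bnelu_pool_bwd_cpp(cache$Z, ddr1, p$bn2_gamma, p$bn2_beta,
                            cache$b2$mean, cache$b2$inv_std, N, Tn, hp$p1)
  g$bn2_gamma <- as.numeric(bb2$dgamma); g$bn2_beta <- as.numeric(bb2$dbeta)
  bl <- eegnet_block1_bwd(cache$M0, p$Wt, p$bn1_gamma, p$bn1_beta,
                          cache$bl_mean, cache$bl_inv_std, p$Wd,
                          bb2$dX, N, C, Tn, FALSE)
  g$Wd <- bl$dWd
  g$bn1_gamma <- as.numeric(bl$dgamma); g$bn1_beta <- as.numeric(bl$dbeta)
  g$Wt <- bl$dWt
  g
}

## ---- CNN-LSTM-family forward/backward ----
# x: array (N, T, C)

cnnlstm_fwd <- function(model, x, training = TRUE) {
  hp <- model$hp; p <- model$params
  N <- dim(x)[1L]; Tn <- dim(x)[2L]; C <- dim(x)[3L]
  stopifnot(C == hp$chans, Tn == hp$samples)
  X0 <- matrix(x, N * Tn, C)
  c1 <- conv1d_fwd(X0, N, Tn, p$W1, p$bc1)
  d1 <- dropout_fwd(c1$out, hp$dropout, training)
  a1 <- lrelu_fwd(d1$out, hp$alpha)
  mp <- pool_max_fwd(a1$out, N, Tn, 2L)
  Tp <- mp$T1
  c2 <- conv1d_fwd(mp$out, N, Tp, p$W2, p$bc2)
  d2 <- dropout_fwd(c2$out, hp$dropout, training)
  a2 <- lrelu_fwd(d2$out, hp$alpha)
  l1 <- lstm_fwd(array(a2$out, c(N, Tp, 64L)), p$Wl1, p$bl1, TRUE)
  c3 <- conv1d_fwd(matrix(l1$out, N * Tp, 64L), N, Tp, p$W3, p$bc3)
  d3 <- dropout_fwd(c3$out, hp$dropout, training)
  a3 <- lrelu_fwd(d3$out, hp$alpha)
  l2 <- lstm_fwd(array(a3$out, c(N, Tp, 64L)), p$Wl2, p$bl2, FALSE)
  d4 <- dropout_fwd(l2$out, hp$dropout, training)
  z1 <- sweep(d4$out %*% p$Wd1, 2L, p$bd1, "+")
  a4 <- lrelu_fwd(z1, hp$alpha)
  logits <- sweep(a4$out %*% p$Wd2, 2L, p$bd2, "+")
  list(logits = logits,
       cache = list(N = N, Tn = Tn, Tp = Tp, X0 = X0, c1 = c1, d1 = d1,
                    a1 = a1, mp = mp, c2 = c2, d2 = d2, a2 = a2, l1 = l1,
                    c3 = c3, d3 = d3, a3 = a3, l2 = l2, d4 = d4, a4 = a4),
       bn_updates = NULL)
}

cnnlstm_bwd <- function(model, cache, dlogits) {
  hp <- model$hp; p <- model$params
  N <- cache$N; Tn <- cache$Tn; Tp <- cache$Tp
  g <- list()
  g$bd2 <- colSums(dlogits)
  g$Wd2 <- crossprod(cache$a4$out, dlogits)
  da4 <- lrelu_bwd(dlogits %*% t(p$Wd2), cache$a4)
  g$bd1 <- colSums(da4)
  g$Wd1 <- crossprod(cache$d4$out, da4)
  dd4 <- dropout_bwd(da4 %*% t(p$Wd1), cache$d4)
  lb2 <- lstm_bwd(dd4, cache$l2, p$Wl2, FALSE)
  g$Wl2 <- lb2$dW; g$bl2 <- lb2$db
  da3 <- lrelu_bwd(matrix(lb2$dX, N * Tp, 64L), cache$a3)
  dd3 <- dropout_bwd(da3, cache$d3)
  cb3 <- conv1d_bwd(dd3, cache$c3, N, Tp, p$W3)
  g$W3 <- cb3$dW; g$bc3 <- cb3$db
  lb1 <- lstm_bwd(array(cb3$dX, c(N, Tp, 64L)), cache$l1, p$Wl1, TRUE)
  g$Wl1 <- lb1$dW; g$bl1 <- lb1$db
  da2 <- lrelu_bwd(matrix(lb1$dX, N * Tp, 64L), cache$a2)
  dd2 <- dropout_bwd(da2, cache$d2)
  cb2 <- conv1d_bwd(dd2, cache$c2, N, Tp, p$W2)
  g$W2 <- cb2$dW; g$bc2 <- cb2$db
  dmp <- pool_max_bwd(cb2$dX, cache$mp, N, Tn, 128L)
  da1 <- lrelu_bwd(dmp, cache$a1)
  dd1 <- dropout_bwd(da1, cache$d1)
  cb1 <- conv1d_bwd(dd1, cache$c1, N, Tn, p$W1, need_dx = FALSE)
  g$W1 <- cb1$dW; g$bc1 <- cb1$db
  g
}

model_forward <- function(model, x, training = TRUE) {
  if (model$family == "eegnet") eegnet_fwd(model, x, training)
  else cnnlstm_fwd(model, x, training)
}

model_backward <- function(model, cache, dlogits) {
  if (model$family == "eegnet") eegnet_bwd(model, cache, dlogits)
  else cnnlstm_bwd(model, cache, dlogits)
}

## ---- Nadam optimizer ----

nadam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

nadam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- lr * (beta1 * mhat + (1 - beta1) / (1 - beta1^t) * gr) /
      (sqrt(vhat) + eps)
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

## ---- training loop ----

# Convert epoch data to the family's input layout.
model_input <- function(family, data) {
  if (family == "eegnet") data                     # (N, C, T)
  else aperm(data, c(1L, 3L, 2L))                  # (N, T, C)
}

#' Train an instantiated model with the cyclical-learning-rate loop
#'
#' Minimizes categorical cross-entropy by mini-batch gradient descent
#' with the Nadam optimizer under a triangular cyclical learning-rate
#' schedule. Deterministic for a fixed configuration seed.
#'
#' @param graph a `model_graph`.
#' @param epochs_x an `epoch_array` (already standardized), or a plain
#'   array in the model's input layout.
#' @param labels zero-based integer labels (taken from `epochs_x` when
#'   it is an `epoch_array`).
#' @param cfg a [train_config()].
#' @return A `vep_model` with trained parameters and a `history` data
#'   frame (epoch, mean loss, learning rate).
#' @export
train_model <- function(graph, epochs_x, labels = NULL, cfg = train_config()) {
  if (inherits(epochs_x, "epoch_array")) {
    labels <- epochs_x$labels
    x <- model_input(graph$family, epochs_x$data)
  } else x <- epochs_x
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= graph$n_classes))
    stop("label out of range [0, ", graph$n_classes, ")")
  N <- dim(x)[1L]
  model <- instantiate_model(graph, seed = cfg$seed)
  opt <- nadam_init(model$params)
  iters_per_epoch <- max(1L, ceiling(N / cfg$batch_size))
  step_size <- cfg$clr_step_multiplier * iters_per_epoch
  iter <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     lr = numeric(0))
  rng <- mix_seed(cfg$seed, 41)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(mix_seed(rng, ep), sample.int(N))
    losses <- numeric(0)
    set.seed(mix_seed(rng, ep, 2))   # dropout stream for this epoch
    for (b in seq_len(iters_per_epoch)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, N)]
      xb <- if (graph$family == "eegnet") x[idx, , , drop = FALSE]
        else x[idx, , , drop = FALSE]
      lr <- clr_schedule(iter, cfg, step_size)
      fw <- model_forward(model, xb, training = TRUE)
      if (!is.null(fw$bn_updates))
        model$bn_state <- fw$bn_updates
      sx <- softmax_xent(fw$logits, labels[idx])
      if (!is.finite(sx$loss))
        stop("divergence: non-finite loss at epoch ", ep)
      grads <- model_backward(model, fw$cache, sx$dlogits)
      st <- nadam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$state
      iter <- iter + 1L
      losses <- c(losses, sx$loss)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   lr = clr_schedule(iter - 1L, cfg,
                                                     step_size)))
  }
  model$history <- hist
  model
}

#' Predict class probabilities / labels with a trained model
#'
#' Runs the forward pass in inference mode (dropout off, batch-norm
#' running statistics).
#'
#' @param model a trained `vep_model`.
#' @param epochs_x an `epoch_array` or plain input array.
#' @param batch_size evaluation batch size (default 512).
#' @return A list with `probs` (matrix `[n x n_classes]`) and `labels`
#'   (zero-based argmax predictions).
#' @export
predict_model <- function(model, epochs_x, batch_size = 512L) {
  x <- if (inherits(epochs_x, "epoch_array"))
    model_input(model$family, epochs_x$data) else epochs_x
  N <- dim(x)[1L]
  probs <- matrix(0, N, model$graph$n_classes)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    probs[idx, ] <- softmax_rows(fw$logits)
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first") - 1L)
}
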