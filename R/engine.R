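# Dense-linear-algebra training engine for the two model families.
#
# Activations flow through 2-D matrices whose row index enumerates
# (batch, space/time) and whose column index enumerates features, so
# every convolution becomes a BLAS matrix product:
#   * temporal convolutions use a banded [T x T*F] weight expansion,
#   * depthwise/pointwise/1-D convolutions use im2col-style slices,
#   * recurrent layers loop over time with a single gate matmul per step.
# Each layer exposes a forward pass that caches what its backward pass
# needs; gradients are verified against finite differences in the test
# suite.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

he_uniform <- function(fan_in, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

## ---- banded temporal convolution (same padding, no bias) ----

# Index template mapping kernel taps into a [T x T] band.
band_template <- function(T, k) {
  pad <- (k - 1L) %/% 2L
  s <- rep(seq_len(T), times = T)      # output position? rows = input pos
  # entries: B[s, t] = W[s - t + pad + 1]
  t <- rep(seq_len(T), each = T)
  kk <- s - t + pad + 1L
  keep <- kk >= 1L & kk <= k
  list(s = s[keep], t = t[keep], k = kk[keep], T = T, kk_n = k)
}

band_matrix <- function(W, tpl) {
  # W: k x F -> B: T x (T*F), columns grouped by filter (t fastest)
  F <- ncol(W)
  B <- matrix(0, tpl$T, tpl$T * F)
  for (f in seq_len(F))
    B[cbind(tpl$s, tpl$t + (f - 1L) * tpl$T)] <- W[tpl$k, f]
  B
}

band_grad <- function(dB, tpl, k, F) {
  dW <- matrix(0, k, F)
  for (f in seq_len(F)) {
    vals <- dB[cbind(tpl$s, tpl$t + (f - 1L) * tpl$T)]
    dW[, f] <- dW[, f] + as.numeric(rowsum(vals, tpl$k, reorder = TRUE))
  }
  dW
}

conv_band_fwd <- function(X, W, tpl) {
  # X: rows x T, W: k x F -> rows x (T*F)
  B <- band_matrix(W, tpl)
  list(out = X %*% B, B = B, X = X)
}

conv_band_bwd <- function(dY, cache, tpl, W) {
  dX <- dY %*% t(cache$B)
  dB <- crossprod(cache$X, dY)
  dW <- band_grad(dB, tpl, nrow(W), ncol(W))
  list(dX = dX, dW = dW)
}

## ---- grouped batch normalization ----

# Columns of M are grouped in blocks of `groupT` per feature. Batch
# statistics are taken over all rows and the group's columns; the
# backward pass recomputes xhat from the cached layer input.
bn_fwd <- function(M, gamma, beta, groupT, run_mean, run_var,
                   training = TRUE, momentum = 0.9, eps = 1e-5) {
  r <- bn_group_fwd_cpp(M, gamma, beta, as.integer(groupT),
                        run_mean, run_var, training, momentum, eps)
  r$groupT <- groupT
  r$mean <- as.numeric(r$mean)
  r$inv_std <- as.numeric(r$inv_std)
  r$run_mean <- as.numeric(r$run_mean)
  r$run_var <- as.numeric(r$run_var)
  r
}

bn_bwd <- function(M, dY, cache, gamma) {
  r <- bn_group_bwd_cpp(M, dY, gamma, cache$mean, cache$inv_std,
                        as.integer(cache$groupT))
  list(dX = r$dX, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

## ---- elementwise pieces ----

elu_fwd <- function(X, alpha = 1) elu_fwd_cpp(X, alpha)

elu_bwd <- function(dY, out, alpha = 1) elu_bwd_cpp(dY, out, alpha)

lrelu_fwd <- function(X, alpha) {
  neg <- X < 0
  out <- X
  out[neg] <- alpha * X[neg]
  list(out = out, neg = neg, alpha = alpha)
}

lrelu_bwd <- function(dY, cache) {
  dX <- dY
  dX[cache$neg] <- dY[cache$neg] * cache$alpha
  dX
}

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

## ---- pooling along the time axis ----
# X: (N*T) x M with row index n + N*(t-1); trims T to a multiple of p.

pool_avg_fwd <- function(X, N, T, p) {
  T1 <- T %/% p
  A <- array(X, c(N, T, ncol(X)))
  out <- array(0, c(N, T1, ncol(X)))
  for (q in seq_len(p)) out <- out + A[, seq(q, T1 * p, by = p), , drop = FALSE]
  out <- out / p
  list(out = matrix(out, N * T1, ncol(X)), T1 = T1)
}

pool_avg_bwd <- function(dY, N, T, p, M) {
  T1 <- T %/% p
  dA <- array(0, c(N, T, M))
  dO <- array(dY, c(N, T1, M))
  for (q in seq_len(p)) dA[, seq(q, T1 * p, by = p), ] <- dO / p
  matrix(dA, N * T, M)
}

pool_max_fwd <- function(X, N, T, p) {
  stopifnot(p == 2L)
  T1 <- T %/% 2L
  A <- array(X, c(N, T, ncol(X)))
  a1 <- A[, seq(1L, 2L * T1, by = 2L), , drop = FALSE]
  a2 <- A[, seq(2L, 2L * T1, by = 2L), , drop = FALSE]
  first <- a1 >= a2
  out <- pmax(a1, a2)
  list(out = matrix(out, N * T1, ncol(X)), first = first, T1 = T1)
}

pool_max_bwd <- function(dY, cache, N, T, M) {
  T1 <- cache$T1
  dA <- array(0, c(N, T, M))
  dO <- array(dY, c(N, T1, M))
  dA[, seq(1L, 2L * T1, by = 2L), ] <- dO * cache$first
  dA[, seq(2L, 2L * T1, by = 2L), ] <- dO * !cache$first
  matrix(dA, N * T, M)
}

## ---- softmax cross-entropy ----

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

softmax_xent <- function(logits, y) {
  # y: zero-based labels
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / n, probs = P)
}
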