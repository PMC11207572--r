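test_that("discretize produces valid normalized histograms", {
  d <- discretize(c(0, 1, 2, 3), 2)
  expect_equal(d$probabilities, c(0.5, 0.5))
  expect_false(d$degenerate)
  set.seed(1)
  x <- rnorm(500)
  d2 <- discretize(x, 16)
  expect_equal(sum(d2$probabilities), 1)
  expect_length(d2$bin_edges, 17)
  dc <- discretize(rep(2, 10), 8)
  expect_true(dc$degenerate)
  expect_equal(sum(dc$probabilities > 0), 1)
  expect_error(discretize(x, 1), "n_bins")
})

test_that("histogram entropy of a Gaussian matches the analytic value", {
  set.seed(42)
  x <- rnorm(10000)
  h <- chan_entropy(discretize(x, 64))
  binwidth <- diff(range(x)) / 64
  analytic <- 0.5 * log(2 * pi * exp(1)) - log(binwidth)
  expect_lt(abs(h - analytic), 0.1)
})

test_that("entropy follows the discrete formula", {
  expect_equal(chan_entropy(rep(0.25, 4)), log(4))
  expect_equal(chan_entropy(c(1, 0, 0)), 0)
  p <- c(0.4, 0.1, 0.1, 0.4)
  expect_equal(chan_entropy(p), -sum(p * log(p)))
})

test_that("KLD is nonnegative, asymmetric and zero iff identical", {
  P <- c(0.5, 0.5); Q <- c(0.25, 0.75)
  expect_equal(kld(P, P), 0)
  expect_equal(kld(P, Q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(kld(P, Q), 4), 0.1438)
  expect_false(isTRUE(all.equal(kld(P, Q), kld(Q, P))))
  expect_gt(kld(Q, P), 0)
  expect_error(kld(c(0.5, 0.5), c(1, 0)), "undefined")
})

test_that("mutual information obeys the independence and dependence limits", {
  # independent: product joint
  px <- c(0.3, 0.7); py <- c(0.6, 0.4)
  expect_equal(mutual_information(outer(px, py)), 0, tolerance = 1e-12)
  # perfectly dependent: diagonal mass -> marginal entropy
  pd <- diag(c(0.2, 0.3, 0.5))
  expect_equal(mutual_information(pd), chan_entropy(c(0.2, 0.3, 0.5)))
  j <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  expect_equal(round(mutual_information(j), 4), 0.1927)
  # bounded by min marginal entropy
  expect_lte(mutual_information(j),
             min(chan_entropy(rowSums(j)), chan_entropy(colSums(j))) + 1e-9)
})

test_that("joint_distribution marginals are consistent", {
  set.seed(2)
  x <- rnorm(2000); y <- x + rnorm(2000)
  jd <- joint_distribution(x, y, 16)
  expect_equal(sum(jd$probabilities), 1)
  expect_equal(rowSums(jd$probabilities), jd$marginal_x$probabilities)
  expect_equal(colSums(jd$probabilities), jd$marginal_y$probabilities)
})

test_that("the pairwise matrix is symmetric with entropy diagonal", {
  cfg <- tiny_cfg(n_channels = 6L, per_subject = 30L, n_samples = 100L)
  ds <- generate_dataset(cfg)$dataset
  m <- pairwise_mutin_matrix(ds, n_bins = 16)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m >= -1e-12))
  expect_identical(rownames(m), ds$channel_names)
  # duplicated channel: I(X; X) == H(X)
  x <- matrix(rnorm(5000), ncol = 1)
  xx <- cbind(A = x, B = x)
  m2 <- pairwise_mutin_matrix(xx, n_bins = 32)
  expect_equal(m2[1, 2], m2[1, 1], tolerance = 1e-9)
  # independent channels: small finite-sample bias only
  set.seed(9)
  ind <- cbind(A = rnorm(1e5), B = rnorm(1e5))
  m3 <- pairwise_mutin_matrix(ind, n_bins = 64)
  expect_lt(m3[1, 2], 0.05)
  expect_error(pairwise_mutin_matrix(x, n_bins = 16), "2 channels")
})

test_that("the estimator is stable between 1e5 and 1e6 pooled samples", {
  set.seed(5)
  n <- 1e6
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  i_small <- mutual_information(joint_distribution(x[1:1e5], y[1:1e5], 64))
  i_large <- mutual_information(joint_distribution(x, y, 64))
  expect_lt(abs(i_small - i_large) / i_large, 0.05)
})

test_that("greedy selection at target 2 equals the exhaustive pair argmax", {
  cfg <- tiny_cfg(n_channels = 8L, per_subject = 40L, n_samples = 150L,
                  shared_fraction = 0.8, snr_db = 5)
  ds <- generate_dataset(cfg)$dataset
  m <- pairwise_mutin_matrix(ds, n_bins = 32)
  sel <- select_channels(m, 2L)
  mm <- unclass(m); diag(mm) <- -Inf
  best <- which(mm == max(mm), arr.ind = TRUE)[1, ]
  expect_setequal(sel$channels, rownames(m)[best])
  expect_error(select_channels(m, 1L), "target_size")
  expect_error(select_channels(m, 9L), "target_size")
})

test_that("greedy triple matches the exhaustive subset oracle and the ground truth", {
  cfg <- tiny_cfg(n_channels = 8L, n_informative = 3L, per_subject = 60L,
                  n_samples = 200L, shared_fraction = 0.8, snr_db = 5)
  ds <- generate_dataset(cfg)$dataset
  m <- pairwise_mutin_matrix(ds, n_bins = 32)
  sel <- select_channels(m, 3L)
  # oracle: maximize total pairwise mutual information over all 56 triples
  triples <- combn(8, 3)
  score <- apply(triples, 2, function(s) sum(m[s, s][upper.tri(diag(3))]))
  best <- triples[, which.max(score)]
  expect_setequal(sel$channels, rownames(m)[best])
  expect_setequal(sel$channels, cfg$informative_channels)
})

test_that("selection exhausts all channels at full target size", {
  m <- matrix(runif(25), 5, 5); m <- (m + t(m)) / 2
  dimnames(m) <- list(LETTERS[1:5], LETTERS[1:5])
  class(m) <- c("mutin_matrix", "matrix")
  sel <- select_channels(m, 5L)
  expect_setequal(sel$channels, LETTERS[1:5])
  expect_length(sel$criterion, 5L)
  expect_false(anyDuplicated(sel$channels) > 0)
})
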