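# Small synthetic configurations used across the suite.

tiny_cfg <- function(n_channels = 8L, n_informative = 3L, n_classes = 5L,
                     per_subject = 45L, n_subjects = 2L, n_samples = 200L,
                     seed = 3L, ...) {
  synth_config(
    n_subjects = n_subjects,
    per_subject_counts = rep(as.integer(per_subject), n_subjects),
    subject_order = seq_len(n_subjects),
    n_classes = n_classes, n_channels = n_channels, n_samples = n_samples,
    channel_names = paste0("CH", seq_len(n_channels)),
    informative_channels = paste0("CH", seq_len(n_informative)),
    seed = seed, ...)
}

# Finite-difference gradient check over a sample of parameters.
gradcheck_worst <- function(graph, x, y, seed = 7, n_per_param = 4,
                            eps = 1e-6) {
  m <- instantiate_model(graph, seed = seed)
  fw <- vepdecode:::model_forward(m, x, training = TRUE)
  sx <- vepdecode:::softmax_xent(fw$logits, y)
  gr <- vepdecode:::model_backward(m, fw$cache, sx$dlogits)
  worst <- 0
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(n_per_param, length(p)))
    for (j in idx) {
      m2 <- m; m2$params[[nm]][j] <- p[j] + eps
      m3 <- m; m3$params[[nm]][j] <- p[j] - eps
      f2 <- vepdecode:::softmax_xent(vepdecode:::model_forward(m2, x, TRUE)$logits, y)$loss
      f3 <- vepdecode:::softmax_xent(vepdecode:::model_forward(m3, x, TRUE)$logits, y)$loss
      num <- (f2 - f3) / (2 * eps)
      ana <- gr[[nm]][j]
      worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
    }
  }
  worst
}
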