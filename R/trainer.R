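#' Training loop configuration
#'
#' Bundles the optimizer/schedule contract: categorical cross-entropy
#' minimized by Nadam under a triangular cyclical learning rate (CLR)
#' oscillating between `clr_low` and `clr_high` with a half-period of
#' `clr_step_multiplier` times the iterations per epoch. The default
#' epoch count (30) is a desk-scale setting for CPU-sized experiments;
#' full-scale runs use 1000 epochs with the same batch size of 440.
#'
#' @param epochs training epochs (default 30; full-scale 1000).
#' @param batch_size mini-batch size (default 440).
#' @param clr_low,clr_high learning-rate bounds (defaults 1e-7, 1e-3).
#' @param clr_step_multiplier CLR half-period in epochs-worth of
#'   iterations (default 8).
#' @param seed seed controlling weight initialization, shuffling and
#'   dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 440L,
                         clr_low = 1e-7, clr_high = 1e-3,
                         clr_step_multiplier = 8L, seed = 1L) {
  stopifnot(clr_low > 0, clr_low < clr_high, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 clr_low = clr_low, clr_high = clr_high,
                 clr_step_multiplier = as.integer(clr_step_multiplier),
                 seed = as.integer(seed)), class = "train_config")
}

#' Triangular cyclical learning rate
#'
#' Linear ramp from `clr_low` at iteration 0 up to `clr_high` at
#' iteration `step_size`, back down to `clr_low` at `2 * step_size`,
#' repeating with period `2 * step_size`.
#'
#' @param iteration zero-based global iteration counter.
#' @param cfg a [train_config()].
#' @param step_size half-period in iterations; defaults to
#'   `cfg$clr_step_multiplier` (i.e. one iteration per epoch).
#' @return The learning rate at `iteration`.
#' @export
clr_schedule <- function(iteration, cfg = train_config(),
                         step_size = cfg$clr_step_multiplier) {
  stopifnot(step_size > 0)
  cycle <- floor(1 + iteration / (2 * step_size))
  x <- abs(iteration / step_size - 2 * cycle + 1)
  cfg$clr_low + (cfg$clr_high - cfg$clr_low) * pmax(0, 1 - x)
}

#' Shuffled k-fold cross-validation splits
#'
#' Partitions `n` indices into `k` shuffled folds whose sizes differ by
#' at most one; each round trains on the complement of its test fold.
#'
#' @param n number of observations.
#' @param k folds (default 10).
#' @param seed shuffle seed.
#' @param labels optional zero-based labels for stratified folds.
#' @return List of `k` lists with `train` and `test` index vectors.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L, labels = NULL) {
  if (k < 2L || n < k) stop("need k >= 2 and n >= k")
  fold_of <- integer(n)
  if (!is.null(labels)) {
    # stratified: deal each class's shuffled members round-robin
    ord <- with_seed(mix_seed(seed, 51), {
      idx <- sample.int(n)
      unlist(split(idx, labels[idx]), use.names = FALSE)
    })
    fold_of[ord] <- rep_len(seq_len(k), n)
  } else {
    ord <- with_seed(mix_seed(seed, 51), sample.int(n))
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold_of[ord] <- rep.int(seq_len(k), sizes)
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Leave-one-subject-out validation rounds
#'
#' One round per subject: the round's test set is that subject's
#' segments and its training set is everyone else's. Rounds rotate
#' starting from the highest subject ID (test order e.g. 6, 1, 2, 3,
#' 4, 5 for subjects 1..6).
#'
#' @param subjects integer subject ID per segment.
#' @return List of rounds with `train`, `test` and `test_subject`.
#' @export
losov_split <- function(subjects) {
  us <- sort(unique(subjects))
  if (length(us) < 2L) stop("at least 2 distinct subjects are required")
  test_order <- c(us[length(us)], us[-length(us)])
  lapply(test_order, function(s)
    list(train = which(subjects != s), test = which(subjects == s),
         test_subject = s))
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true,predicted zero-based integer label vectors of equal
#'   length.
#' @param n_classes number of classes.
#' @return A `confusion_matrix`: integer matrix `[true x predicted]`.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  if (length(true) &&
      (min(true, predicted) < 0L || max(true, predicted) >= n_classes))
    stop("labels must lie in [0, ", n_classes, ")")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = NULL, predicted = NULL))
  for (i in seq_along(true))
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L, predicted[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Accuracy from a confusion matrix, in percent
#'
#' Without `label`, the overall multiclass accuracy
#' `trace / total x 100`. With a `label`, the one-vs-rest reading
#' `(TP + TN) / (TP + TN + FP + FN) x 100` for that class.
#'
#' @param cm a `confusion_matrix`.
#' @param label optional zero-based class for the one-vs-rest variant.
#' @return Accuracy percentage.
#' @export
accuracy <- function(cm, label = NULL) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  if (is.null(label)) return(sum(diag(cm)) / total * 100)
  l <- label + 1L
  tp <- cm[l, l]
  fn <- sum(cm[l, ]) - tp
  fp <- sum(cm[, l]) - tp
  tn <- total - tp - fn - fp
  (tp + tn) / total * 100
}

#' Run a full evaluation protocol on a segment set
#'
#' Chains the enhancement pipeline and a classifier over
#' cross-validation splits: bad-channel repair and artifact-span
#' rejection on the whole set, windowed epoching, then per split a
#' standardization scaler fitted on the training fold only (unless
#' `scale = FALSE`, the ablation arm), model training and test-fold
#' prediction.
#'
#' @param ds a [segment_set()] (already channel-subset if desired).
#' @param model_kind `"eegnet"` or `"cnn_lstm"`.
#' @param window analysis window (see [make_epochs()]).
#' @param scheme `"kfold"` or `"losov"`.
#' @param cfg a [train_config()].
#' @param k folds for the k-fold scheme (default 10).
#' @param scale fit/apply the per-channel scaler (default TRUE); FALSE
#'   bypasses the standardization stage.
#' @param repair,reject run the bad-channel repair / span-rejection
#'   stages (defaults TRUE).
#' @param z_threshold span-rejection cutoff (default 6).
#' @return An `eval_report`: per-split accuracies (percent), their
#'   mean, per-split confusion matrices, fitted scaler statistics (the
#'   leakage audit trail), split descriptions and the window label.
#' @export
evaluate_protocol <- function(ds, model_kind = c("eegnet", "cnn_lstm"),
                              window = "0:440",
                              scheme = c("kfold", "losov"),
                              cfg = train_config(), k = 10L,
                              scale = TRUE, repair = TRUE, reject = TRUE,
                              z_threshold = 6) {
  model_kind <- match.arg(model_kind)
  scheme <- match.arg(scheme)
  if (repair) ds <- detect_and_repair_bad_channels(ds)$dataset
  if (reject) ds <- reject_spans(ds, z_threshold)$dataset
  ep <- make_epochs(ds, window)
  d <- dim(ep$data)
  splits <- if (scheme == "kfold") kfold_split(d[1L], k, seed = cfg$seed)
    else losov_split(ep$subjects)
  builder <- if (model_kind == "eegnet") build_eegnet else build_cnn_lstm
  graph <- builder(chans = d[2L], samples = d[3L], n_classes = ep$n_classes)
  accs <- numeric(length(splits))
  cms <- vector("list", length(splits))
  scalers <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr <- ep; tr$data <- ep$data[sp$train, , , drop = FALSE]
    tr$labels <- ep$labels[sp$train]; tr$subjects <- ep$subjects[sp$train]
    te <- ep; te$data <- ep$data[sp$test, , , drop = FALSE]
    te$labels <- ep$labels[sp$test]; te$subjects <- ep$subjects[sp$test]
    if (scale) {
      sc <- fit_scaler(tr)
      tr <- apply_scaler(tr, sc)
      te <- apply_scaler(te, sc)
      scalers[[i]] <- sc
    }
    cfg_i <- cfg
    cfg_i$seed <- mix_seed(cfg$seed, 100L + i)
    model <- tryCatch(train_model(graph, tr, cfg = cfg_i),
                      error = function(e)
                        stop("split ", i, ": ", conditionMessage(e)))
    pred <- predict_model(model, te)
    cms[[i]] <- confusion_matrix(te$labels, pred$labels, ep$n_classes)
    accs[i] <- accuracy(cms[[i]])
  }
  structure(list(model_kind = model_kind, scheme = scheme,
                 window = paste0(ep$window[1L], ":", ep$window[2L]),
                 fold_accuracy = accs, mean_accuracy = mean(accs),
                 confusions = cms, scalers = scalers,
                 splits = lapply(splits, function(s)
                   list(n_train = length(s$train), n_test = length(s$test),
                        test_subject = s$test_subject)),
                 scaled = scale),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$model_kind, ", ", x$scheme, ", window ",
      x$window, if (!x$scaled) " (scaler bypassed)", "\n", sep = "")
  cat("  per-split accuracy [%]: ",
      paste(sprintf("%.1f", x$fold_accuracy), collapse = " "), "\n", sep = "")
  cat("  mean accuracy: ", sprintf("%.1f", x$mean_accuracy), "%\n", sep = "")
  invisible(x)
}
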