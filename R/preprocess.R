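#' Detect and repair bad channels
#'
#' A channel is flagged bad when its pooled standard deviation falls
#' below `flat_threshold` (near-flat electrode) or when its maximum
#' absolute correlation with every other channel falls below
#' `corr_threshold` (disconnected from the scalp field). Flagged
#' channels are replaced, segment by segment, with the mean of the
#' three good channels most correlated with the pooled montage, so the
#' repaired trace carries plausible neighborhood signal.
#'
#' @param ds a [segment_set()] with at least 3 channels.
#' @param flat_threshold absolute sd floor in microvolts; `NULL`
#'   (default) uses `1e-3 x` the median channel sd.
#' @param corr_threshold minimum max-|correlation| with the rest of the
#'   montage (default 0.02; shared line noise and evoked structure keep
#'   healthy channels well above this).
#' @return A list with `dataset` (repaired) and `bad_channels`
#'   (character vector of repaired channel names).
#' @export
detect_and_repair_bad_channels <- function(ds, flat_threshold = NULL,
                                           corr_threshold = 0.02) {
  stopifnot(inherits(ds, "segment_set"))
  C <- n_channels(ds)
  if (C < 3L) stop("at least 3 channels are required")
  pooled <- matrix(aperm(ds$data, c(3L, 1L, 2L)), ncol = C)
  sds <- apply(pooled, 2L, stats::sd)
  if (is.null(flat_threshold)) flat_threshold <- 1e-3 * stats::median(sds)
  cm <- suppressWarnings(stats::cor(pooled))
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  maxcor <- apply(abs(cm), 2L, max)
  bad <- which(sds < flat_threshold | maxcor < corr_threshold)
  if (length(bad) == C)
    stop("unrecoverable data: every channel is flagged bad")
  if (length(bad)) {
    good <- setdiff(seq_len(C), bad)
    for (b in bad) {
      donors <- good[order(abs(cm[b, good]), decreasing = TRUE)][1:min(3L, length(good))]
      # segment-wise repair: mean of the donor channels
      ds$data[, b, ] <- apply(ds$data[, donors, , drop = FALSE], c(1L, 3L), mean)
    }
  }
  list(dataset = ds, bad_channels = ds$channel_names[bad])
}

#' Reject segments containing extreme-amplitude spans
#'
#' Standardizes every channel against robust pooled statistics (median
#' and MAD, so the artifacts being hunted cannot mask themselves by
#' inflating the scale) and drops any segment containing a sample with
#' `|z| > z_threshold`. An infinite threshold is the identity.
#'
#' @param ds a [segment_set()].
#' @param z_threshold positive z-score cutoff (default 6).
#' @return A list with `dataset` (clean segments) and `rejected`
#'   (integer indices of the dropped segments).
#' @export
reject_spans <- function(ds, z_threshold = 6) {
  stopifnot(inherits(ds, "segment_set"), z_threshold > 0)
  C <- n_channels(ds)
  pooled <- matrix(aperm(ds$data, c(3L, 1L, 2L)), ncol = C)
  mu <- apply(pooled, 2L, stats::median)
  sdv <- apply(pooled, 2L, stats::mad)
  sdv[sdv == 0] <- Inf
  rejected <- integer(0)
  if (is.finite(z_threshold)) {
    # max |z| per segment, channel-wise standardization
    z <- abs(sweep(sweep(ds$data, 2L, mu), 2L, sdv, "/"))
    mx <- apply(z, 1L, max)
    rejected <- which(mx > z_threshold)
  }
  if (length(rejected) == n_segments(ds))
    stop("unrecoverable data: every segment was rejected")
  ds2 <- if (length(rejected)) subset_segments(ds, -rejected) else ds
  list(dataset = ds2, rejected = rejected)
}

#' Slice segments into a fixed post-stimulus window
#'
#' Extracts the half-open window `[start_ms, end_ms)` from every
#' segment; at 1 kHz sample `i` (1-based) represents millisecond
#' `i - 1`, so `"360:440"` yields 80 samples. Labels and subjects are
#' carried over, one epoch per segment.
#'
#' @param ds a [segment_set()].
#' @param window either a length-2 numeric `(start_ms, end_ms)` or a
#'   string `"start:end"`; the canonical analysis windows are
#'   `"20:240"`, `"20:350"`, `"20:440"`, `"40:200"`, `"40:360"`,
#'   `"130:350"`, `"130:440"`, `"240:440"`, `"360:440"` and the full
#'   `"0:440"`.
#' @return An `epoch_array`: list with `data`
#'   `[n_epochs x n_channels x n_samples]`, `labels`, `subjects`,
#'   `channel_names` and `window`.
#' @export
make_epochs <- function(ds, window = c(0, n_samples(ds))) {
  stopifnot(inherits(ds, "segment_set"))
  w <- parse_window(window)
  fs_ms <- ds$sampling_rate_hz / 1000
  max_ms <- n_samples(ds) / fs_ms
  if (w[1L] < 0 || w[2L] > max_ms || w[1L] >= w[2L])
    stop("window must satisfy 0 <= start < end <= ", max_ms, " ms")
  idx <- (round(w[1L] * fs_ms) + 1L):round(w[2L] * fs_ms)
  structure(list(data = ds$data[, , idx, drop = FALSE],
                 labels = ds$labels, subjects = ds$subjects,
                 channel_names = ds$channel_names,
                 n_classes = ds$n_classes, window = w),
            class = "epoch_array")
}

parse_window <- function(window) {
  if (is.character(window)) {
    parts <- as.numeric(strsplit(window, ":", fixed = TRUE)[[1L]])
    if (length(parts) != 2L || anyNA(parts))
      stop("window string must look like \"360:440\"")
    window <- parts
  }
  as.numeric(window)
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> ", d[1L], " epochs x ", d[2L], " channels x ",
      d[3L], " samples, window [", x$window[1L], ", ", x$window[2L],
      ") ms\n", sep = "")
  invisible(x)
}

#' Fit per-channel standardization statistics
#'
#' Estimates each channel's mean and variance by pooling all epochs and
#' time points: the mean is the plain average and the variance uses the
#' unbiased `N - 1` denominator, `N` being the number of pooled values
#' (epochs x time points).
#'
#' @param epochs an `epoch_array` from [make_epochs()].
#' @return A `scaler_stats`: list with `mean`, `var` (per channel) and
#'   `n` (pooled count).
#' @export
fit_scaler <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  N <- d[1L] * d[3L]
  if (N < 2L) stop("need at least 2 pooled values per channel")
  pooled <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), ncol = d[2L])
  mu <- colMeans(pooled)
  v <- colSums(sweep(pooled, 2L, mu)^2) / (N - 1L)
  if (any(v == 0))
    stop("degenerate channel (zero variance): ",
         paste(epochs$channel_names[v == 0], collapse = ", "))
  structure(list(mean = mu, var = v, n = N,
                 channel_names = epochs$channel_names),
            class = "scaler_stats")
}

#' Standardize epochs with fitted channel statistics
#'
#' Applies `(x - mean) / sd` per channel. Labels, subjects and epoch
#' length are preserved; typically the statistics are fitted on
#' training epochs only and applied unchanged to validation epochs.
#'
#' @param epochs an `epoch_array`.
#' @param s a `scaler_stats` fitted on epochs with the same montage.
#' @return The standardized `epoch_array`.
#' @export
apply_scaler <- function(epochs, s) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(s, "scaler_stats"))
  if (dim(epochs$data)[2L] != length(s$mean) ||
      !identical(epochs$channel_names, s$channel_names))
    stop("scaler channel set does not match the epochs")
  epochs$data <- sweep(sweep(epochs$data, 2L, s$mean), 2L, sqrt(s$var), "/")
  epochs
}

#' Average epochs within classes to obtain evoked responses
#'
#' @param epochs an `epoch_array` with at least one epoch per class.
#' @return Numeric array `[n_classes x n_channels x n_samples]` of
#'   class-mean (evoked) responses.
#' @export
average_evoked <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  K <- epochs$n_classes
  d <- dim(epochs$data)
  missing <- setdiff(seq_len(K) - 1L, unique(epochs$labels))
  if (length(missing))
    stop("missing class(es) with no epochs: ",
         paste(missing, collapse = ", "))
  out <- array(0, c(K, d[2L], d[3L]))
  for (c in seq_len(K)) {
    idx <- which(epochs$labels == c - 1L)
    out[c, , ] <- if (length(idx) == 1L) epochs$data[idx, , ]
      else colMeans(epochs$data[idx, , , drop = FALSE], dims = 1L)
  }
  out
}

#' Canonical analysis windows
#'
#' The nine post-stimulus windows used for time-interval analysis plus
#' the full segment.
#'
#' @return Character vector of `"start:end"` window strings.
#' @export
analysis_windows <- function() {
  c("20:240", "20:350", "20:440", "40:200", "40:360",
    "130:350", "130:440", "240:440", "360:440")
}
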