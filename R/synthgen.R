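#' Configuration for the synthetic visual-EEG generator
#'
#' Describes a synthetic corpus that emulates the structure of a
#' 6-subject, 40-class, 128-channel visual EEG study: class-dependent
#' evoked responses concentrated in an "informative" channel subset,
#' 1/f background noise band-limited to 5--95 Hz with a 50 Hz notch,
#' residual 50 Hz line contamination, and optional artifact spans and
#' bad channels. Ground truth for every injected structure is returned
#' alongside the data, so downstream stages can be tested against it.
#'
#' @param n_subjects number of subjects (default 6).
#' @param per_subject_counts segments per subject, in acquisition order;
#'   defaults to `c(1995, 1985, 1996, 1996, 1996, 1996)` (11,964 total).
#' @param subject_order subject IDs in acquisition order, matching
#'   `per_subject_counts`; default `c(4, 1, 6, 3, 2, 5)`.
#' @param n_classes number of balanced stimulus classes (default 40).
#' @param n_channels montage size (default 128, using [montage_128()]).
#' @param n_samples samples per segment (default 440).
#' @param sampling_rate_hz sampling rate (default 1000).
#' @param channel_names optional explicit channel labels.
#' @param informative_channels names of channels carrying the evoked
#'   class signal; default [discriminant_54()] for the 128-channel
#'   montage, otherwise the last 40% of the montage.
#' @param snr_db evoked-to-noise power ratio in dB on informative
#'   channels (default 5).
#' @param shared_fraction fraction of evoked variance common to all
#'   informative channels, in `[0, 1]` (default 0.8); the remainder is a
#'   channel-specific but class-locked residual waveform.
#' @param evoked_amp_uv peak amplitude of the shared class template in
#'   microvolts before the subject gain (default 10).
#' @param line_noise_amp amplitude of the residual 50 Hz sinusoid in
#'   microvolts, common phase across channels within a segment
#'   (default 0.5).
#' @param channel_gain_sd standard deviation of log-normal per-channel
#'   hardware gains (default 0 = homogeneous channels). Nonzero values
#'   emulate heterogeneous electrode scaling, the condition under which
#'   per-channel standardization matters.
#' @param channel_offset_uv standard deviation (microvolts) of fixed
#'   per-channel DC offsets (default 0), emulating unequalized
#'   electrode baselines.
#' @param artifact_rate probability that a segment receives a
#'   high-amplitude artifact span (default 0).
#' @param bad_channel_list channel names replaced by near-flat noise.
#' @param seed master seed; every segment derives its own RNG stream
#'   from it, so any subset of segments can be regenerated
#'   independently.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 6L,
                         per_subject_counts = c(1995L, 1985L, 1996L,
                                                1996L, 1996L, 1996L),
                         subject_order = c(4L, 1L, 6L, 3L, 2L, 5L),
                         n_classes = 40L,
                         n_channels = 128L,
                         n_samples = 440L,
                         sampling_rate_hz = 1000,
                         channel_names = NULL,
                         informative_channels = NULL,
                         snr_db = 5,
                         shared_fraction = 0.8,
                         evoked_amp_uv = 10,
                         line_noise_amp = 0.5,
                         channel_gain_sd = 0,
                         channel_offset_uv = 0,
                         artifact_rate = 0,
                         bad_channel_list = character(0),
                         seed = 1L) {
  if (length(per_subject_counts) != n_subjects)
    stop("per_subject_counts length must equal n_subjects")
  if (length(subject_order) != n_subjects)
    stop("subject_order length must equal n_subjects")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 128L) montage_128() else
      paste0("CH", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels)
    stop("channel_names length must equal n_channels")
  if (is.null(informative_channels)) {
    informative_channels <- if (n_channels == 128L) discriminant_54() else
      channel_names[seq.int(max(1L, n_channels - ceiling(0.4 * n_channels) + 1L),
                            n_channels)]
  }
  if (!all(informative_channels %in% channel_names))
    stop("informative_channels must be a subset of the channel list")
  if (!all(bad_channel_list %in% channel_names))
    stop("bad_channel_list must be a subset of the channel list")
  structure(list(
    n_subjects = as.integer(n_subjects),
    per_subject_counts = as.integer(per_subject_counts),
    subject_order = as.integer(subject_order),
    n_classes = as.integer(n_classes),
    n_channels = as.integer(n_channels),
    n_samples = as.integer(n_samples),
    sampling_rate_hz = sampling_rate_hz,
    channel_names = channel_names,
    informative_channels = informative_channels,
    snr_db = snr_db,
    shared_fraction = shared_fraction,
    evoked_amp_uv = evoked_amp_uv,
    line_noise_amp = line_noise_amp,
    channel_gain_sd = channel_gain_sd,
    channel_offset_uv = channel_offset_uv,
    artifact_rate = artifact_rate,
    bad_channel_list = bad_channel_list,
    seed = as.integer(seed)), class = "synth_config")
}

# Deterministic 31-bit sub-seed from a stream of integers.
mix_seed <- function(...) {
  ks <- as.numeric(c(...))
  h <- 104729
  for (k in ks) h <- (h * 31 + k + 1) %% 2147483629
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One ERP-like waveform: Gaussian-windowed oscillations with latencies
# stratified over the segment so every analysis window sees class
# energy. Zero-mean, unit peak.
erp_waveform <- function(n_samples, fs, seed, n_components = 4L) {
  with_seed(seed, {
    t_ms <- (seq_len(n_samples) - 1L) / fs * 1000
    span <- n_samples / fs * 1000
    # component centers: one per quarter of the usable post-onset range
    # (about 40 ms .. span-20 ms for standard segments, scaled down for
    # short ones)
    lo <- min(40, 0.15 * span); hi <- span - min(20, 0.1 * span)
    if (hi <= lo) { lo <- 0.1 * span; hi <- 0.9 * span }
    edges <- seq(lo, hi, length.out = n_components + 1L)
    w <- numeric(n_samples)
    for (i in seq_len(n_components)) {
      center <- stats::runif(1, edges[i], edges[i + 1L])
      width <- stats::runif(1, 15, 40)                 # ms
      freq <- stats::runif(1, 5, 45)                   # Hz, inside 5-95 band
      phase <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1)
      w <- w + a * exp(-((t_ms - center)^2) / (2 * width^2)) *
        cos(2 * pi * freq * (t_ms - center) / 1000 + phase)
    }
    w <- w - mean(w)
    w / max(abs(w))
  })
}

#' Deterministic evoked template for one class
#'
#' Builds the shared class template: a zero-mean, unit-peak sum of four
#' Gaussian-windowed oscillations (5--45 Hz carriers inside the 5--95 Hz
#' band) whose latencies are stratified across the segment, mimicking a
#' canonical sequence of early, middle and late evoked components.
#'
#' @param class_id zero-based class index.
#' @param cfg a [synth_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return Numeric waveform of length `cfg$n_samples` with
#'   `max(abs(.)) == 1`.
#' @export
make_class_template <- function(class_id, cfg, seed = cfg$seed) {
  if (class_id < 0 || class_id >= cfg$n_classes)
    stop("class_id must lie in [0, ", cfg$n_classes, ")")
  erp_waveform(cfg$n_samples, cfg$sampling_rate_hz,
               mix_seed(seed, 1, class_id))
}

# Channel-specific class-locked residual waveform.
residual_template <- function(class_id, chan_idx, cfg, seed = cfg$seed) {
  erp_waveform(cfg$n_samples, cfg$sampling_rate_hz,
               mix_seed(seed, 2, class_id, chan_idx))
}

#' Ground-truth structure for a synthetic configuration
#'
#' Precomputes everything deterministic the generator injects: the
#' per-class shared templates, channel-specific residual templates,
#' subject gains, per-channel hardware gains, per-subject label
#' sequences and the background-noise scale implied by `snr_db`.
#'
#' @param cfg a [synth_config()].
#' @return A `synth_ground_truth` list.
#' @export
synth_ground_truth <- function(cfg) {
  K <- cfg$n_classes
  Tn <- cfg$n_samples
  inf_idx <- match(cfg$informative_channels, cfg$channel_names)
  templates <- t(vapply(seq_len(K) - 1L, make_class_template,
                        numeric(Tn), cfg = cfg))
  # residuals [class x informative-channel x sample]
  residuals <- array(0, c(K, length(inf_idx), Tn))
  for (c in seq_len(K)) for (j in seq_along(inf_idx))
    residuals[c, j, ] <- residual_template(c - 1L, inf_idx[j], cfg)
  subject_gains <- with_seed(mix_seed(cfg$seed, 3),
                             stats::runif(cfg$n_subjects, 0.8, 1.2))
  names(subject_gains) <- as.character(cfg$subject_order)
  channel_gains <- if (cfg$channel_gain_sd > 0) {
    with_seed(mix_seed(cfg$seed, 4),
              exp(stats::rnorm(cfg$n_channels, 0, cfg$channel_gain_sd)))
  } else rep(1, cfg$n_channels)
  channel_offsets <- if (cfg$channel_offset_uv > 0) {
    with_seed(mix_seed(cfg$seed, 9),
              stats::rnorm(cfg$n_channels, 0, cfg$channel_offset_uv))
  } else rep(0, cfg$n_channels)
  # balanced, shuffled per-subject label sequences
  labels <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    n_i <- cfg$per_subject_counts[s]
    if (n_i < K)
      stop("configuration error: subject count ", n_i,
           " is below n_classes (", K, "); balance impossible")
    labels[[s]] <- with_seed(mix_seed(cfg$seed, 5, s),
                             sample(rep_len(seq_len(K) - 1L, n_i)))
  }
  # evoked power averaged over classes sets the noise scale
  p_evoked <- cfg$evoked_amp_uv^2 * mean(apply(templates, 1, stats::var))
  sigma_noise <- sqrt(p_evoked / 10^(cfg$snr_db / 10))
  structure(list(
    informative_channels = cfg$informative_channels,
    informative_idx = inf_idx,
    templates = templates,
    residuals = residuals,
    subject_gains = subject_gains,
    channel_gains = channel_gains,
    channel_offsets = channel_offsets,
    subject_labels = labels,
    sigma_noise = sigma_noise,
    artifacts = data.frame(subject = integer(0), segment = integer(0),
                           channel = integer(0), start = integer(0),
                           length = integer(0)),
    bad_channels = cfg$bad_channel_list), class = "synth_ground_truth")
}

# 1/f amplitude mask over rfft bins: band-limited 5-95 Hz, 50 Hz notch.
noise_spectrum_mask <- function(n_samples, fs) {
  nf <- n_samples %/% 2L
  freqs <- seq_len(nf) * fs / n_samples      # positive-frequency bins
  amp <- ifelse(freqs >= 5 & freqs <= 95 & !(freqs >= 48 & freqs <= 52),
                1 / sqrt(freqs), 0)
  list(nf = nf, amp = amp)
}

# Generate raw traces for specific segments of one subject (by position
# in cfg$subject_order). Returns [length(seg_idx) x n_channels x n_samples].
gen_segments <- function(cfg, gt, subject_pos, seg_idx) {
  Tn <- cfg$n_samples
  nc <- cfg$n_channels
  fs <- cfg$sampling_rate_hz
  subj_id <- cfg$subject_order[subject_pos]
  g_s <- gt$subject_gains[as.character(subj_id)]
  msk <- noise_spectrum_mask(Tn, fs)
  inf <- gt$informative_idx
  a_sh <- sqrt(cfg$shared_fraction)
  a_re <- sqrt(1 - cfg$shared_fraction)
  tvec <- (seq_len(Tn) - 1L) / fs
  line_carrier <- sin(2 * pi * 50 * tvec)
  line_carrier_q <- cos(2 * pi * 50 * tvec)
  out <- array(0, c(length(seg_idx), nc, Tn))
  labels <- gt$subject_labels[[subject_pos]]
  for (i in seq_along(seg_idx)) {
    si <- seg_idx[i]
    cls <- labels[si] + 1L
    seg <- with_seed(mix_seed(cfg$seed, 6, subject_pos, si), {
      # band-limited 1/f noise, unit sd per channel, then scaled
      ph <- matrix(stats::runif(msk$nf * nc, 0, 2 * pi), msk$nf, nc)
      spec <- matrix(0+0i, Tn, nc)
      spec[2:(msk$nf + 1L), ] <- msk$amp * exp(1i * ph)
      noise <- Re(stats::mvfft(spec, inverse = TRUE))
      noise <- sweep(noise, 2L, apply(noise, 2L, stats::sd), "/")
      x <- t(noise) * gt$sigma_noise                       # [nc x Tn]
      # evoked structure on informative channels
      ev <- cfg$evoked_amp_uv * g_s *
        (a_sh * matrix(gt$templates[cls, ], length(inf), Tn, byrow = TRUE) +
           a_re * gt$residuals[cls, , ])
      x[inf, ] <- x[inf, ] + ev
      # residual line contamination, common phase across the montage
      if (cfg$line_noise_amp > 0) {
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + cfg$line_noise_amp *
          tcrossprod(rep(1, nc), cos(phi) * line_carrier + sin(phi) * line_carrier_q)
      }
      x * gt$channel_gains + gt$channel_offsets
    })
    out[i, , ] <- seg
  }
  out
}

#' Generate one subject's synthetic segments
#'
#' @param cfg a [synth_config()].
#' @param subject_pos position of the subject in `cfg$subject_order`.
#' @param gt optional precomputed [synth_ground_truth()].
#' @return A [segment_set()] for that subject (artifacts not injected).
#' @export
generate_subject <- function(cfg, subject_pos, gt = synth_ground_truth(cfg)) {
  n_i <- cfg$per_subject_counts[subject_pos]
  data <- gen_segments(cfg, gt, subject_pos, seq_len(n_i))
  segment_set(data, gt$subject_labels[[subject_pos]],
              rep(cfg$subject_order[subject_pos], n_i),
              cfg$channel_names, cfg$sampling_rate_hz, cfg$n_classes,
              class_names = if (cfg$n_classes == 40L) stimulus_classes_40())
}

#' Generate a full synthetic dataset with ground truth
#'
#' Materializes every segment of the configured corpus and injects the
#' configured artifacts and bad channels. Each segment is
#' `subject gain x (class template mixed into the informative channels,
#' with a shared component across them plus a channel-specific
#' residual) + 1/f background noise scaled to `snr_db` + a 50 Hz
#' sinusoid`, all times the per-channel hardware gain. Fully
#' reproducible from `cfg$seed`.
#'
#' Note the default 128-channel, 11,964-segment configuration occupies
#' several GiB in memory; reduced configurations are intended for
#' in-memory use, while full-scale channel statistics are available in
#' streaming form through [pool_channel_samples()].
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `dataset` (a [segment_set()]) and
#'   `ground_truth` (a [synth_ground_truth()] including the artifact
#'   registry).
#' @export
generate_dataset <- function(cfg) {
  gt <- synth_ground_truth(cfg)
  parts <- lapply(seq_len(cfg$n_subjects), function(s)
    generate_subject(cfg, s, gt))
  total <- sum(cfg$per_subject_counts)
  data <- array(0, c(total, cfg$n_channels, cfg$n_samples))
  labels <- integer(total)
  subjects <- integer(total)
  off <- 0L
  for (p in parts) {
    rows <- off + seq_len(n_segments(p))
    data[rows, , ] <- p$data
    labels[rows] <- p$labels
    subjects[rows] <- p$subjects
    off <- off + n_segments(p)
  }
  ds <- segment_set(data, labels, subjects, cfg$channel_names,
                    cfg$sampling_rate_hz, cfg$n_classes,
                    class_names = parts[[1L]]$class_names)
  res <- inject_artifacts(ds, cfg)
  res$ground_truth <- modifyList(gt, list(artifacts = res$registry))
  class(res$ground_truth) <- "synth_ground_truth"
  list(dataset = res$dataset, ground_truth = res$ground_truth)
}

#' Inject artifact spans and bad channels into a segment set
#'
#' With probability `cfg$artifact_rate` a segment receives a contiguous
#' high-amplitude span (>= 20 samples, amplitude >= 10 x channel sd) on
#' a random quarter of the montage; channels in `cfg$bad_channel_list`
#' are replaced by near-flat noise throughout. Every injection is
#' recorded in the returned registry. A rate of 0 with no bad channels
#' is the identity.
#'
#' @param ds a [segment_set()].
#' @param cfg a [synth_config()] (fields `artifact_rate`,
#'   `bad_channel_list` and `seed` are used).
#' @param seed seed for the injection draws (default derived from
#'   `cfg$seed`).
#' @return A list with `dataset`, `registry` (data frame of injected
#'   spans) and `bad_channels`.
#' @export
inject_artifacts <- function(ds, cfg, seed = mix_seed(cfg$seed, 7)) {
  reg <- data.frame(subject = integer(0), segment = integer(0),
                    channel = integer(0), start = integer(0),
                    length = integer(0))
  Tn <- n_samples(ds)
  if (cfg$artifact_rate > 0) {
    with_seed(seed, {
      hit <- which(stats::runif(n_segments(ds)) < cfg$artifact_rate)
      for (g in hit) {
        len <- sample(20:min(80L, Tn), 1L)
        start <- sample.int(Tn - len + 1L, 1L)
        chs <- sample.int(n_channels(ds), max(1L, n_channels(ds) %/% 4L))
        for (ch in chs) {
          amp <- 10 * stats::sd(ds$data[g, ch, ])
          ds$data[g, ch, start:(start + len - 1L)] <-
            ds$data[g, ch, start:(start + len - 1L)] +
            amp * sign(stats::runif(1) - 0.5)
          reg <- rbind(reg, data.frame(subject = ds$subjects[g],
                                       segment = g, channel = ch,
                                       start = start, length = len))
        }
      }
    })
  }
  if (length(cfg$bad_channel_list)) {
    bidx <- match(cfg$bad_channel_list, ds$channel_names)
    bidx <- bidx[!is.na(bidx)]
    with_seed(mix_seed(seed, 11), {
      for (ch in bidx)
        ds$data[, ch, ] <- stats::rnorm(n_segments(ds) * Tn, 0, 1e-4)
    })
  }
  list(dataset = ds, registry = reg, bad_channels = cfg$bad_channel_list)
}

#' Pool per-channel samples from the generator without materializing
#' the full corpus
#'
#' Channel statistics (histograms, mutual information) pool every
#' channel across segments and time points. For full-scale
#' configurations this function streams a deterministic, evenly strided
#' subset of segments from each subject and returns the pooled samples
#' as a matrix, avoiding the memory cost of the complete corpus.
#'
#' @param cfg a [synth_config()].
#' @param max_segments total number of segments to draw, spread across
#'   subjects proportionally (default 480).
#' @param gt optional precomputed ground truth.
#' @return Numeric matrix `[n_points x n_channels]` with channel names
#'   as column names.
#' @export
pool_channel_samples <- function(cfg, max_segments = 480L,
                                 gt = synth_ground_truth(cfg)) {
  total <- sum(cfg$per_subject_counts)
  take <- pmax(1L, round(cfg$per_subject_counts / total * max_segments))
  blocks <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    idx <- unique(round(seq(1L, cfg$per_subject_counts[s],
                            length.out = take[s])))
    arr <- gen_segments(cfg, gt, s, idx)       # [n x C x T]
    blocks[[s]] <- matrix(aperm(arr, c(3L, 1L, 2L)),   # [(T*n) x C]
                          ncol = cfg$n_channels)
  }
  out <- do.call(rbind, blocks)
  colnames(out) <- cfg$channel_names
  out
}

#' Structural manifest for a synthetic configuration
#'
#' Returns the dataset manifest implied by a configuration without
#' generating any data: per-subject segment counts in acquisition
#' order, totals, channel list, class names and provenance.
#'
#' @param cfg a [synth_config()].
#' @return A list mirroring the on-disk manifest schema.
#' @export
dataset_manifest <- function(cfg) {
  list(format_version = 1L,
       n_segments = sum(cfg$per_subject_counts),
       n_channels = cfg$n_channels,
       n_samples = cfg$n_samples,
       n_classes = cfg$n_classes,
       sampling_rate_hz = cfg$sampling_rate_hz,
       channel_names = cfg$channel_names,
       class_names = if (cfg$n_classes == 40L) stimulus_classes_40(),
       subjects = data.frame(subject = cfg$subject_order,
                             n_segments = cfg$per_subject_counts),
       provenance = list(kind = "synthetic", seed = cfg$seed,
                         snr_db = cfg$snr_db,
                         shared_fraction = cfg$shared_fraction,
                         informative_channels = cfg$informative_channels))
}
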