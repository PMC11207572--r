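#' Labeled multichannel EEG segment collections
#'
#' A `segment_set` bundles fixed-length EEG segments with their class
#' labels, subject identifiers and channel names. Data are stored as a
#' 3-D numeric array `[n_segments x n_channels x n_samples]` in
#' microvolts. Labels are zero-based class indices in `[0, n_classes)`;
#' at 1 kHz the sample index `i` (1-based) covers the half-open
#' millisecond interval `[i-1, i)`, so a 440-sample segment spans
#' 0--440 ms after stimulus onset.
#'
#' @param data numeric 3-D array `[n_segments x n_channels x n_samples]`.
#' @param labels integer vector, one zero-based class label per segment.
#' @param subjects integer vector, one subject ID per segment.
#' @param channel_names character vector of unique channel labels in
#'   10-20 extended nomenclature (e.g. `"CP1"`, `"POz"`, `"FCC1h"`),
#'   one per channel, same order as the second array dimension.
#' @param sampling_rate_hz positive sampling rate, default 1000.
#' @param n_classes number of stimulus classes, default 40.
#' @param class_names optional character vector of length `n_classes`.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(data, labels, subjects, channel_names,
                        sampling_rate_hz = 1000, n_classes = 40L,
                        class_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [segments x channels x samples]")
  n_seg <- dim(data)[1L]
  n_ch <- dim(data)[2L]
  labels <- as.integer(labels)
  subjects <- as.integer(subjects)
  if (length(labels) != n_seg || length(subjects) != n_seg)
    stop("labels/subjects length (", length(labels), "/", length(subjects),
         ") must equal n_segments (", n_seg, ")")
  if (n_seg > 0 && (anyNA(labels) || min(labels) < 0L || max(labels) >= n_classes))
    stop("labels must lie in [0, ", n_classes, ")")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != n_ch)
    stop("channel_names length (", length(channel_names),
         ") must equal n_channels (", n_ch, ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  if (!is.null(class_names) && length(class_names) != n_classes)
    stop("class_names must have length n_classes")
  structure(
    list(data = data, labels = labels, subjects = subjects,
         channel_names = channel_names,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         n_classes = as.integer(n_classes),
         class_names = class_names),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<segment_set> ", d[1L], " segments x ", d[2L], " channels x ",
      d[3L], " samples @ ", x$sampling_rate_hz, " Hz\n", sep = "")
  cat("  classes: ", x$n_classes,
      "; subjects: ", paste(sort(unique(x$subjects)), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.segment_set <- function(x) dim(x$data)

n_segments <- function(ds) dim(ds$data)[1L]
n_channels <- function(ds) dim(ds$data)[2L]
n_samples <- function(ds) dim(ds$data)[3L]

#' Restrict a segment set to named channels
#'
#' Returns a new set containing only the requested channels, in the
#' order given by `names`. Segment order, labels and subjects are
#' preserved, so the operation commutes with segment slicing and is
#' idempotent.
#'
#' @param ds a [segment_set()].
#' @param names character vector of channel names, all present in
#'   `ds$channel_names`.
#' @return A `segment_set` with `length(names)` channels.
#' @export
subset_channels <- function(ds, names) {
  stopifnot(inherits(ds, "segment_set"))
  names <- as.character(names)
  idx <- match(names, ds$channel_names)
  if (anyNA(idx))
    stop("unknown channel name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  segment_set(ds$data[, idx, , drop = FALSE], ds$labels, ds$subjects,
              names, ds$sampling_rate_hz, ds$n_classes, ds$class_names)
}

#' Slice a segment set by segment index
#'
#' @param ds a [segment_set()].
#' @param idx integer vector of segment indices (1-based).
#' @return A `segment_set` holding the selected segments.
#' @export
subset_segments <- function(ds, idx) {
  stopifnot(inherits(ds, "segment_set"))
  segment_set(ds$data[idx, , , drop = FALSE], ds$labels[idx],
              ds$subjects[idx], ds$channel_names, ds$sampling_rate_hz,
              ds$n_classes, ds$class_names)
}

#' Standard 128-channel montage and the discriminant 54-channel subset
#'
#' `montage_128()` returns the 128 actiCAP-style 10-20 extended channel
#' labels used as the default montage, ordered roughly frontal to
#' occipital. `discriminant_54()` returns the 54-channel discriminant
#' subset concentrated over the central, parietal and occipital
#' cortices that the selection stage targets by default.
#'
#' @return Character vector of channel labels (length 128 / 54).
#' @export
montage_128 <- function() {
  c(
    # frontal-polar / anterior-frontal
    "Fp1", "Fpz", "Fp2", "AFp1", "AFp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "AFF5h", "AFF1h", "AFF2h", "AFF6h",
    # frontal
    "F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10",
    "FFT7h", "FFC5h", "FFC3h", "FFC1h", "FFC2h", "FFC4h", "FFC6h", "FFT8h",
    # fronto-temporal / fronto-central
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "FTT9h", "FTT7h", "FCC5h", "FCC3h", "FCC1h", "FCC2h", "FCC4h", "FCC6h",
    "FTT8h", "FTT10h",
    # temporal / central
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TTP7h", "CCP5h", "CCP3h", "CCP1h", "CCP2h", "CCP4h", "CCP6h", "TTP8h",
    # temporo-parietal / centro-parietal
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "TPP9h", "TPP7h", "CPP5h", "CPP3h", "CPP1h", "CPP2h", "CPP4h", "CPP6h",
    "TPP8h", "TPP10h",
    # parietal
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PPO9h", "PPO5h", "PPO1h", "PPO2h", "PPO6h", "PPO10h",
    # parieto-occipital / occipital
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "POO9h", "POO1", "POO2", "POO10h",
    "O1", "O11h", "Oz", "O12h", "O2",
    "I1", "Iz", "I2"
  )
}

#' @rdname montage_128
#' @export
discriminant_54 <- function() {
  c("FCC1h", "FCC2h", "FCC4h",
    "FC1", "FC2",
    "C1", "C2", "C3", "Cz", "C4", "C5", "C6",
    "CP1", "CP2", "CP3", "CPz", "CP4",
    "CCP1h", "CCP2h", "CCP3h", "CCP4h",
    "O1", "Oz", "O2", "I1", "O11h", "O12h", "I2",
    "Pz", "P1", "P2", "P3", "P4", "P5", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "PO9", "PO10",
    "PPO9h", "PPO5h", "PPO1h", "PPO2h", "PPO6h", "PPO10h",
    "POO1", "POO2", "POO9h", "POO10h", "Iz")
}

#' Default 40-class stimulus label names
#'
#' Names for the 40 object categories used as visual stimuli.
#'
#' @return Character vector of length 40.
#' @export
stimulus_classes_40 <- function() {
  c("cats", "sorrels", "elephants", "fish", "dogs", "airliners", "brooms",
    "pandas", "canoes", "phones", "mugs", "convertibles", "computers",
    "fungi", "locomotives", "espresso", "chairs", "butterflies", "golf",
    "piano", "iron", "daisy", "jacks", "mailbags", "capuchin", "missiles",
    "mittens", "bikes", "tents", "pajama", "parachutes", "pools", "radios",
    "cameras", "guitar", "guns", "shoes", "bananas", "pizzas", "watches")
}
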