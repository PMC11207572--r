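#' Save a segment set to a directory
#'
#' Persists one raw binary array file per subject plus a JSON manifest.
#' Arrays are written as little-endian 32-bit IEEE floats in row-major
#' order `[segment][channel][sample]`, so byte output is deterministic
#' for a given input. The manifest records per-subject segment counts,
#' the channel list, sampling rate, class names and provenance.
#'
#' @param ds a [segment_set()].
#' @param path directory to write into (created if missing).
#' @param provenance optional list describing where the data came from
#'   (e.g. the synthetic generator configuration), stored verbatim.
#' @return The manifest file path, invisibly.
#' @export
save_dataset <- function(ds, path, provenance = NULL) {
  stopifnot(inherits(ds, "segment_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  subjects <- sort(unique(ds$subjects))
  files <- list()
  for (s in subjects) {
    idx <- which(ds$subjects == s)
    fn <- sprintf("subject_%02d.bin", s)
    con <- file(file.path(path, fn), "wb")
    on.exit(close(con), add = TRUE)
    # row-major [segment][channel][sample]: permute so sample varies fastest
    block <- aperm(ds$data[idx, , , drop = FALSE], c(3L, 2L, 1L))
    writeBin(as.numeric(block), con, size = 4L, endian = "little")
    close(con)
    on.exit()
    files[[as.character(s)]] <- list(
      file = fn, subject = s, n_segments = length(idx),
      labels = ds$labels[idx])
  }
  manifest <- list(
    format_version = 1L,
    n_segments = n_segments(ds),
    n_channels = n_channels(ds),
    n_samples = n_samples(ds),
    n_classes = ds$n_classes,
    sampling_rate_hz = ds$sampling_rate_hz,
    channel_names = ds$channel_names,
    class_names = ds$class_names,
    dtype = "float32-le",
    order = "segment,channel,sample",
    subjects = unname(files),
    provenance = provenance)
  mpath <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mpath)
}

#' Load a segment set from a directory
#'
#' Reads the JSON manifest written by [save_dataset()] and the
#' per-subject binary array files, cross-checking array sizes against
#' the manifest counts.
#'
#' @param path directory containing `manifest.json` and `.bin` files.
#' @return A [segment_set()].
#' @export
load_dataset <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    stop("I/O error: no manifest.json in ", path)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  n_seg <- m$n_segments
  n_ch <- m$n_channels
  n_sa <- m$n_samples
  subj_tab <- m$subjects
  if (sum(subj_tab$n_segments) != n_seg)
    stop("manifest validation error: per-subject counts sum to ",
         sum(subj_tab$n_segments), " but n_segments is ", n_seg)
  data <- array(0, c(n_seg, n_ch, n_sa))
  labels <- integer(n_seg)
  subjects <- integer(n_seg)
  offset <- 0L
  for (i in seq_len(nrow(subj_tab))) {
    fn <- file.path(path, subj_tab$file[i])
    if (!file.exists(fn)) stop("I/O error: missing array file ", fn)
    ns <- subj_tab$n_segments[i]
    expect_vals <- ns * n_ch * n_sa
    if (file.info(fn)$size != expect_vals * 4L)
      stop("shape/manifest mismatch for ", fn, ": expected ",
           expect_vals * 4L, " bytes, found ", file.info(fn)$size)
    con <- file(fn, "rb")
    vals <- readBin(con, numeric(), n = expect_vals, size = 4L,
                    endian = "little")
    close(con)
    block <- aperm(array(vals, c(n_sa, n_ch, ns)), c(3L, 2L, 1L))
    rows <- offset + seq_len(ns)
    data[rows, , ] <- block
    labels[rows] <- as.integer(subj_tab$labels[[i]])
    subjects[rows] <- subj_tab$subject[i]
    offset <- offset + ns
  }
  ds <- segment_set(data, labels, subjects, m$channel_names,
                    m$sampling_rate_hz, m$n_classes,
                    class_names = m$class_names)
  ds
}
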