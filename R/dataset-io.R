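#' A long EDA recording
#'
#' @param values_uS Numeric vector of conductance values in microsiemens.
#' @param sampling_rate_hz Sampling frequency in Hz.
#' @param label Optional 0/1 label for the whole recording (labels are per
#'   task, not per sample).
#' @param source_id Identifier string.
#' @return An object of class `eda_recording`.
#' @export
eda_recording <- function(values_uS, sampling_rate_hz, label = NULL,
                          source_id = "") {
  values_uS <- as.numeric(values_uS)
  if (length(values_uS) < 1L) stop("recording must contain at least 1 sample")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (!is.null(label) && !label %in% c(0, 1)) stop("label must be 0 or 1")
  structure(list(
    values_uS = values_uS,
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    label = if (is.null(label)) NULL else as.integer(label),
    source_id = as.character(source_id)
  ), class = "eda_recording")
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("EDA recording \"%s\": %d samples at %g Hz (%.1f min)%s\n",
              x$source_id, length(x$values_uS), x$sampling_rate_hz,
              length(x$values_uS) / x$sampling_rate_hz / 60,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Segment a recording into fixed-length overlapping windows
#'
#' Window `k` (0-based) covers samples `[k * stride, k * stride + window)`
#' in 0-based half-open coordinates, giving
#' `floor((L - W) / S) + 1` windows; a trailing partial window is dropped,
#' never padded.  A 5-minute recording at 5 Hz (1500 samples) cut with a
#' 600-sample window and 300-sample stride yields 4 windows, so 80 such
#' recordings yield 320 sequences.
#'
#' @param recording An [eda_recording()] (or bare numeric vector).
#' @param window_samples Window length W in samples.
#' @param stride_samples Hop S between window starts in samples (the overlap
#'   is `W - S`).
#' @return Numeric matrix with one window per row (0 rows when the
#'   recording is shorter than the window, with a warning).
#' @export
segment_recording <- function(recording, window_samples,
                              stride_samples = window_samples) {
  values <- if (inherits(recording, "eda_recording")) recording$values_uS
    else as.numeric(recording)
  w <- as.integer(window_samples)
  s <- as.integer(stride_samples)
  if (w < 1L) stop("window_samples must be >= 1")
  if (s < 1L) stop("stride_samples must be >= 1")
  l <- length(values)
  if (w > l) {
    warning("window (", w, ") exceeds recording length (", l,
            "); no windows produced")
    return(matrix(numeric(0), 0L, w))
  }
  n_win <- (l - w) %/% s + 1L
  out <- matrix(0, n_win, w)
  for (k in seq_len(n_win)) {
    out[k, ] <- values[((k - 1L) * s + 1L):((k - 1L) * s + w)]
  }
  out
}

#' Segment several recordings into one labeled dataset
#'
#' Applies [segment_recording()] to each recording; every window inherits
#' the label of its source recording.
#'
#' @param recordings List of [eda_recording()] objects.
#' @inheritParams segment_recording
#' @return An `eda_dataset` with provenance `"windowed-recording"`.
#' @export
segment_recordings <- function(recordings, window_samples, stride_samples) {
  pieces <- lapply(recordings, segment_recording, window_samples,
                   stride_samples)
  labels <- unlist(lapply(seq_along(recordings), function(i) {
    lab <- recordings[[i]]$label
    rep(if (is.null(lab)) NA_integer_ else lab, nrow(pieces[[i]]))
  }))
  seqs <- do.call(rbind, pieces)
  eda_dataset(seqs, labels = if (anyNA(labels)) NULL else labels,
              provenance = "windowed-recording")
}

#' Normalize dataset sequences
#'
#' Per-sequence z-scoring (the default preprocessing for the classifier)
#' maps each sequence to zero mean and unit standard deviation; a constant
#' sequence maps to all zeros.  Labels are untouched.
#'
#' @param dataset An `eda_dataset` or numeric matrix.
#' @param mode `"zscore"` or `"none"`.
#' @return Object of the same type with transformed sequences.
#' @export
normalize_sequences <- function(dataset, mode = c("zscore", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(dataset)
  x <- if (inherits(dataset, "eda_dataset")) dataset$sequences else
    as.matrix(dataset)
  x <- zscore_rows(x)
  if (inherits(dataset, "eda_dataset")) {
    dataset$sequences <- x
    dataset
  } else {
    x
  }
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  centered <- x - mu
  sdv <- sqrt(rowMeans(centered^2))
  sdv[sdv < 1e-12] <- Inf  # constant rows -> all zeros
  centered / sdv
}

#' Read a single-column conductance CSV as a recording
#'
#' The file must contain one numeric conductance column in microsiemens
#' (header optional; the first column is used).
#'
#' @param path CSV file path.
#' @param sampling_rate_hz Sampling frequency the file was recorded at.
#' @param label Optional 0/1 label.
#' @return An [eda_recording()].
#' @export
load_recording_csv <- function(path, sampling_rate_hz, label = NULL) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  df <- utils::read.csv(path, header = has_header)
  values <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(values)) stop("malformed CSV: non-numeric conductance values")
  eda_recording(values, sampling_rate_hz, label = label,
                source_id = basename(path))
}

#' Save / load an EDA dataset as CSV + JSON sidecar
#'
#' `save_eda_dataset()` writes `<basename>.csv` (one row per sequence, one
#' column per sample, no header) and `<basename>.json` holding labels,
#' provenance, seed and the configuration snapshot.  `load_eda_dataset()`
#' reverses it; the round trip reproduces values, labels and metadata.
#'
#' @param dataset An `eda_dataset`.
#' @param basename Path prefix (without extension) to write to.
#' @return `save_eda_dataset()` returns `basename` invisibly;
#'   `load_eda_dataset()` returns the `eda_dataset`.
#' @export
save_eda_dataset <- function(dataset, basename) {
  stopifnot(inherits(dataset, "eda_dataset"))
  utils::write.table(dataset$sequences, paste0(basename, ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(
    labels = dataset$labels,
    spike_counts = dataset$spike_counts,
    provenance = dataset$provenance,
    seed = if (is.null(dataset$seed) || is.na(dataset$seed)) NULL else
      dataset$seed,
    n_sequences = nrow(dataset$sequences),
    sequence_len = ncol(dataset$sequences),
    config = config_to_plain(dataset$config)
  )
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(basename)
}

#' @rdname save_eda_dataset
#' @export
load_eda_dataset <- function(basename) {
  seqs <- as.matrix(utils::read.csv(paste0(basename, ".csv"), header = FALSE))
  dimnames(seqs) <- NULL
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  if (!is.null(meta$labels) && length(meta$labels) != nrow(seqs)) {
    stop("sidecar labels length (", length(meta$labels),
         ") does not match number of sequences (", nrow(seqs), ")")
  }
  if (!is.null(meta$sequence_len) && meta$sequence_len != ncol(seqs)) {
    stop("sidecar sequence_len does not match CSV")
  }
  ds <- eda_dataset(seqs, labels = meta$labels,
                    provenance = meta$provenance %||% "unknown",
                    config = config_from_plain(meta$config))
  ds$spike_counts <- meta$spike_counts
  ds$seed <- if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_ else
    as.integer(meta$seed)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_to_plain <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  unclass(cfg)
}

config_from_plain <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  x <- as.list(x)
  drift <- as.list(x$baseline_drift %||% list())
  do.call(eda_sim_config, c(
    x[setdiff(names(x), c("baseline_drift", "seed"))],
    list(baseline_drift = drift,
         seed = if (is.null(x$seed) || is.na(x$seed)) NULL else x$seed)
  ))
}
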