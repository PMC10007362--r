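#' Bateman skin conductance response kernel
#'
#' Samples the double-exponential impulse response
#' \deqn{h(t) = g\,(e^{-t/\tau_1} - e^{-t/\tau_2}), \quad \tau_1 > \tau_2 > 0,}
#' the canonical model of a single skin conductance response (SCR): a fast
#' rise governed by `tau2` and a slow recovery governed by `tau1`.  The gain
#' `g` is chosen so the sampled kernel has unit maximum, which makes a spike
#' of amplitude `a` produce an SCR peaking at `a` microsiemens.
#'
#' @param tau1_s Recovery time constant in seconds (`tau1 > tau2`).
#' @param tau2_s Rise time constant in seconds, positive.
#' @param sampling_rate_hz Sampling frequency in Hz.
#' @param duration_s Kernel support to sample; defaults to `10 * tau1_s`,
#'   after which the kernel is negligible.
#'
#' @return Numeric vector `h` with `h[1] = 0` (the onset sample), a single
#'   interior maximum equal to 1, and nonnegative entries.  The analytic
#'   peak time is \eqn{t^* = \tau_1\tau_2/(\tau_1-\tau_2)\,
#'   \log(\tau_1/\tau_2)}.
#' @examples
#' h <- bateman_kernel(2, 0.5, 5)
#' which.max(h)  # sample nearest 0.924 s
#' @export
bateman_kernel <- function(tau1_s, tau2_s, sampling_rate_hz,
                           duration_s = 10 * tau1_s) {
  if (!is.finite(tau1_s) || !is.finite(tau2_s) || tau2_s <= 0) {
    stop("time constants must be positive and finite")
  }
  if (tau1_s <= tau2_s) {
    stop("tau1_s must exceed tau2_s (the kernel is identically zero or ",
         "negative otherwise)")
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  t <- seq(0, duration_s, by = 1 / sampling_rate_hz)
  h <- exp(-t / tau1_s) - exp(-t / tau2_s)
  h / max(h)
}

#' Draw per-segment peak counts for one sequence
#'
#' The number of SCR peaks is drawn from a discrete uniform distribution
#' over the inclusive integer range belonging to the label: 1-5 per minute
#' for the neutral state, 6-20 for the active one (defaults).  With
#' `counts_per = "minute"` one independent count is drawn for every minute
#' of the sequence; with `"sequence"` a single count covers the window.
#'
#' @param label 0 (neutral) or 1 (active).
#' @param config An [eda_sim_config()].
#' @return Integer vector of counts, one per placement segment.
#' @export
draw_peak_counts <- function(label, config) {
  validate_sim_config(config)
  if (!length(label) == 1L || !label %in% c(0, 1)) {
    stop("label must be 0 (neutral) or 1 (active)")
  }
  rng <- if (label == 0) config$neutral_peaks_per_min else
    config$active_peaks_per_min
  n_seg <- if (config$counts_per == "minute") as.integer(sim_minutes(config))
    else 1L
  rng[1] + sample.int(rng[2] - rng[1] + 1L, n_seg, replace = TRUE) - 1L
}

#' Place spike onsets and draw per-peak kernel parameters
#'
#' Within each placement segment, onsets are sampled uniformly at random
#' subject to a minimum spacing; each peak receives its own amplitude
#' (uniform over the configured range) and its own Bateman time constants,
#' redrawn independently for every peak.
#'
#' @param counts_per_segment Integer vector as returned by
#'   [draw_peak_counts()]; segments partition the sequence equally.
#' @param config An [eda_sim_config()].
#' @return An object of class `eda_spike_train`: a list with
#'   `onset_samples` (0-based, strictly increasing), `amplitudes_uS`,
#'   `tau1_s` and `tau2_s`, all of the same length.
#' @export
place_spikes <- function(counts_per_segment, config) {
  validate_sim_config(config)
  counts <- as.integer(counts_per_segment)
  if (any(counts < 0L)) stop("counts must be nonnegative")
  n_seg <- length(counts)
  seg_len <- config$sequence_len_samples %/% n_seg
  gap <- as.integer(ceiling(config$min_peak_spacing_s *
                              config$sampling_rate_hz))
  onsets <- integer(0)
  for (m in seq_len(n_seg)) {
    c_m <- counts[m]
    if (c_m == 0L) next
    if (seg_len - (c_m - 1L) * gap < 1L) {
      stop("cannot place ", c_m, " peaks with spacing >= ", gap,
           " samples in a segment of ", seg_len, " samples")
    }
    seg_start <- (m - 1L) * seg_len
    # keep the global spacing invariant across the segment boundary
    lo <- if (length(onsets) > 0L)
      max(0L, onsets[length(onsets)] + gap - seg_start) else 0L
    avail <- seg_len - lo - (c_m - 1L) * gap
    if (avail < 1L) {
      stop("cannot place ", c_m, " peaks with spacing >= ", gap,
           " samples in the remainder of the segment")
    }
    pos <- sort(sample.int(avail, c_m, replace = TRUE) - 1L)
    onsets <- c(onsets, seg_start + lo + pos + (seq_len(c_m) - 1L) * gap)
  }
  n <- length(onsets)
  tau1 <- stats::runif(n, config$tau1_range_s[1], config$tau1_range_s[2])
  tau2 <- stats::runif(n, config$tau2_range_s[1], config$tau2_range_s[2])
  # tau1 >= tau1_min >= tau2_max >= tau2 by config validation; ties have
  # probability zero but would break the kernel, so nudge if they occur
  eq <- tau1 <= tau2
  if (any(eq)) tau2[eq] <- tau1[eq] * 0.999
  structure(list(
    onset_samples = as.integer(onsets),
    amplitudes_uS = stats::runif(n, config$amplitude_range_uS[1],
                                 config$amplitude_range_uS[2]),
    tau1_s = tau1,
    tau2_s = tau2
  ), class = "eda_spike_train")
}

#' Generate the slowly varying tonic baseline
#'
#' The skin conductance level (SCL) is modeled as a random starting level
#' plus a linear drift and a few low-amplitude sinusoids with periods of at
#' least one minute.  The total variation of the slow component is capped
#' per minute (`baseline_drift$max_tv_uS_per_min`); if the drawn drift
#' exceeds the cap it is rescaled.
#'
#' @param config An [eda_sim_config()].
#' @param n_samples Number of samples to generate.
#' @return Positive numeric vector of length `n_samples` in microsiemens.
#' @export
generate_baseline <- function(config, n_samples = config$sequence_len_samples) {
  validate_sim_config(config)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  d <- config$baseline_drift
  t_s <- (seq_len(n_samples) - 1L) / config$sampling_rate_hz
  level <- stats::runif(1, config$baseline_level_range_uS[1],
                        config$baseline_level_range_uS[2])
  slope <- stats::runif(1, d$slope_range_uS_per_min[1],
                        d$slope_range_uS_per_min[2])
  slow <- slope * t_s / 60
  for (i in seq_len(d$n_sinusoids)) {
    amp <- stats::runif(1, d$amp_range_uS[1], d$amp_range_uS[2])
    period <- stats::runif(1, max(60, d$period_range_s[1]), d$period_range_s[2])
    phase <- stats::runif(1, 0, 2 * pi)
    slow <- slow + amp * sin(2 * pi * t_s / period + phase)
  }
  minutes <- max(t_s[n_samples] / 60, 1e-9)
  tv <- sum(abs(diff(slow))) / minutes
  if (tv > d$max_tv_uS_per_min) slow <- slow * (d$max_tv_uS_per_min / tv)
  level + slow
}

#' Generate one labeled synthetic EDA sequence
#'
#' Assembles a sequence as phasic + tonic + noise: the sparse spike train is
#' convolved with a per-peak Bateman kernel (truncated at the sequence end),
#' added to the slow baseline and to i.i.d. zero-mean Gaussian noise.  All
#' ground truth (spike train, baseline, noise realization) is stored, so the
#' sequence can be reconstructed exactly from its parts.
#'
#' @param label 0 (neutral) or 1 (active).
#' @param config An [eda_sim_config()].
#' @return An object of class `eda_sequence`: a list with `values_uS`,
#'   `label`, `spikes` (an `eda_spike_train`), `baseline_uS`, `noise_uS`
#'   and `noise_sigma_uS`.
#' @examples
#' cfg <- eda_sim_config(seed = 1)
#' set.seed(1)
#' s <- generate_eda_sequence(1, cfg)
#' length(s$values_uS)
#' @export
generate_eda_sequence <- function(label, config) {
  counts <- draw_peak_counts(label, config)
  spikes <- place_spikes(counts, config)
  n <- config$sequence_len_samples
  phasic <- phasic_component(spikes, config)
  baseline <- generate_baseline(config, n)
  noise <- if (config$noise_sigma_uS > 0) {
    stats::rnorm(n, 0, config$noise_sigma_uS)
  } else {
    numeric(n)
  }
  structure(list(
    values_uS = phasic + baseline + noise,
    label = as.integer(label),
    spikes = spikes,
    baseline_uS = baseline,
    noise_uS = noise,
    noise_sigma_uS = config$noise_sigma_uS
  ), class = "eda_sequence")
}

# Sum of shifted, amplitude-scaled unit-max Bateman kernels (the discrete
# convolution h * x for a sparse x), truncated at the sequence end.
phasic_component <- function(spikes, config) {
  n <- config$sequence_len_samples
  phasic <- numeric(n)
  for (i in seq_along(spikes$onset_samples)) {
    h <- bateman_kernel(spikes$tau1_s[i], spikes$tau2_s[i],
                        config$sampling_rate_hz)
    on <- spikes$onset_samples[i]          # 0-based onset
    len <- min(length(h), n - on)
    idx <- on + seq_len(len)
    phasic[idx] <- phasic[idx] + spikes$amplitudes_uS[i] * h[seq_len(len)]
  }
  phasic
}

#' @export
print.eda_sequence <- function(x, ...) {
  cat(sprintf("Synthetic EDA sequence: %d samples, label %d (%s), %d peaks\n",
              length(x$values_uS), x$label,
              if (x$label == 1) "active" else "neutral",
              length(x$spikes$onset_samples)))
  invisible(x)
}

#' Generate a labeled dataset of synthetic EDA sequences
#'
#' Draws labels to match the requested class balance exactly (the number of
#' active sequences is `round(n * balance)`), generates each sequence
#' independently, and shuffles the order.  With a seed (argument or
#' `config$seed`) the result is fully reproducible.
#'
#' @param n_sequences Number of sequences.
#' @param config An [eda_sim_config()].
#' @param balance Fraction of active (label 1) sequences, in `[0, 1]`.
#' @param seed Integer seed; defaults to `config$seed`.  `NULL` leaves the
#'   R random number generator state untouched.
#' @return An object of class `eda_dataset`: a list with `sequences`
#'   (numeric matrix, one row per sequence), `labels` (integer 0/1),
#'   `spike_counts` (ground-truth total peaks per sequence), `config`,
#'   `provenance = "synthetic"` and `seed`.
#' @examples
#' ds <- generate_eda_dataset(4, eda_sim_config(seed = 7))
#' table(ds$labels)
#' @export
generate_eda_dataset <- function(n_sequences, config = eda_sim_config(),
                                 balance = 0.5, seed = config$seed) {
  validate_sim_config(config)
  n <- as.integer(n_sequences)
  if (n < 1L) stop("n_sequences must be >= 1")
  if (balance < 0 || balance > 1) stop("balance must be in [0, 1]")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  n1 <- as.integer(round(n * balance))
  labels <- sample(c(rep(0L, n - n1), rep(1L, n1)))
  seqs <- matrix(0, n, config$sequence_len_samples)
  counts <- integer(n)
  for (i in seq_len(n)) {
    s <- generate_eda_sequence(labels[i], config)
    seqs[i, ] <- s$values_uS
    counts[i] <- length(s$spikes$onset_samples)
  }
  structure(list(
    sequences = seqs,
    labels = labels,
    spike_counts = counts,
    config = config,
    provenance = "synthetic",
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "eda_dataset")
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Construct an EDA dataset from a matrix of sequences
#'
#' @param sequences Numeric matrix, one fixed-length sequence per row.
#' @param labels Integer vector of 0/1 labels, one per row (or `NULL` for
#'   unlabeled data).
#' @param provenance Short string recording where the sequences came from.
#' @param config Optional configuration or source descriptor to snapshot.
#' @return An `eda_dataset`.
#' @export
eda_dataset <- function(sequences, labels = NULL, provenance = "unknown",
                        config = NULL) {
  sequences <- as.matrix(sequences)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(sequences)) {
      stop("length(labels) must equal nrow(sequences)")
    }
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  }
  structure(list(
    sequences = sequences,
    labels = labels,
    spike_counts = NULL,
    config = config,
    provenance = provenance,
    seed = NA_integer_
  ), class = "eda_dataset")
}

#' @export
print.eda_dataset <- function(x, ...) {
  cat(sprintf("EDA dataset: %d sequences x %d samples (%s)\n",
              nrow(x$sequences), ncol(x$sequences), x$provenance))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d neutral, %d active\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  }
  invisible(x)
}
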