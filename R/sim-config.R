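#' Simulation configuration for synthetic EDA sequences
#'
#' Collects every generative parameter of the synthetic electrodermal
#' activity (EDA) model: a sparse sudomotor spike train convolved with
#' per-peak randomized Bateman kernels, added to a slowly varying tonic
#' baseline, plus white Gaussian noise.  Defaults reproduce the study
#' conditions: 5 Hz sampling, 600-sample (2 min) sequences, 1-5 peaks per
#' minute for the neutral state and 6-20 for the active one, kernel time
#' constants tau1 in (1, 40) s and tau2 in (0.2, 1) s redrawn at every peak.
#'
#' @param sampling_rate_hz Sampling frequency in Hz.
#' @param sequence_len_samples Sequence length in samples.
#' @param neutral_peaks_per_min Inclusive integer range of peak counts per
#'   minute for the neutral (label 0) state.
#' @param active_peaks_per_min Inclusive integer range for the active
#'   (label 1) state.  Must be disjoint from, and above, the neutral range.
#' @param tau1_range_s Range of the slow (recovery) time constant, seconds.
#' @param tau2_range_s Range of the fast (rise) time constant, seconds.
#'   Its upper bound may not exceed the lower bound of `tau1_range_s`, so
#'   every peak has tau1 > tau2.
#' @param amplitude_range_uS Range of per-peak SCR amplitudes in
#'   microsiemens; the kernel is normalized to unit maximum so the amplitude
#'   is the height of the resulting conductance peak.
#' @param baseline_level_range_uS Range of the tonic starting level.
#' @param baseline_drift List controlling the slow baseline dynamics:
#'   `slope_range_uS_per_min` (linear drift), `n_sinusoids`,
#'   `period_range_s` (all periods at least 60 s), `amp_range_uS`
#'   (per-sinusoid amplitude), and `max_tv_uS_per_min` (cap on the total
#'   variation of the slow component per minute; the drift is rescaled if
#'   the cap is exceeded).
#' @param noise_sigma_uS Standard deviation of the additive Gaussian noise.
#' @param min_peak_spacing_s Minimum spacing between consecutive spike
#'   onsets, seconds.
#' @param counts_per Whether the peak-count ranges are interpreted per
#'   `"minute"` (one independent draw for each minute of signal, the
#'   default) or per `"sequence"` (a single draw for the whole window).
#' @param seed Optional integer seed giving reproducible datasets.
#'
#' @return An object of class `eda_sim_config` (a validated list).
#' @seealso [generate_eda_sequence()], [generate_eda_dataset()]
#' @examples
#' cfg <- eda_sim_config(seed = 1)
#' cfg$active_peaks_per_min
#' @export
eda_sim_config <- function(sampling_rate_hz = 5,
                           sequence_len_samples = 600L,
                           neutral_peaks_per_min = c(1L, 5L),
                           active_peaks_per_min = c(6L, 20L),
                           tau1_range_s = c(1, 40),
                           tau2_range_s = c(0.2, 1),
                           amplitude_range_uS = c(0.1, 1.0),
                           baseline_level_range_uS = c(2, 10),
                           baseline_drift = list(),
                           noise_sigma_uS = 0.05,
                           min_peak_spacing_s = 1,
                           counts_per = c("minute", "sequence"),
                           seed = NULL) {
  drift_defaults <- list(
    slope_range_uS_per_min = c(-0.1, 0.1),
    n_sinusoids = 2L,
    period_range_s = c(60, 180),
    amp_range_uS = c(0, 0.1),
    max_tv_uS_per_min = 1
  )
  stopifnot(is.list(baseline_drift))
  unknown <- setdiff(names(baseline_drift), names(drift_defaults))
  if (length(unknown) > 0L) {
    stop("unknown baseline_drift fields: ", paste(unknown, collapse = ", "))
  }
  drift <- utils::modifyList(drift_defaults, baseline_drift)

  cfg <- structure(list(
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    sequence_len_samples = as.integer(sequence_len_samples),
    neutral_peaks_per_min = as.integer(neutral_peaks_per_min),
    active_peaks_per_min = as.integer(active_peaks_per_min),
    tau1_range_s = as.numeric(tau1_range_s),
    tau2_range_s = as.numeric(tau2_range_s),
    amplitude_range_uS = as.numeric(amplitude_range_uS),
    baseline_level_range_uS = as.numeric(baseline_level_range_uS),
    baseline_drift = drift,
    noise_sigma_uS = as.numeric(noise_sigma_uS),
    min_peak_spacing_s = as.numeric(min_peak_spacing_s),
    counts_per = match.arg(counts_per),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "eda_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "eda_sim_config"))
  with(cfg, {
    if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
    if (sequence_len_samples < 1L) stop("sequence_len_samples must be >= 1")
    range_ok <- function(r) length(r) == 2L && !anyNA(r) && r[1] <= r[2]
    for (nm in c("neutral_peaks_per_min", "active_peaks_per_min",
                 "tau1_range_s", "tau2_range_s", "amplitude_range_uS",
                 "baseline_level_range_uS")) {
      if (!range_ok(cfg[[nm]])) stop(nm, " must be an ordered length-2 range")
    }
    if (tau1_range_s[1] <= 0 || tau2_range_s[1] <= 0) {
      stop("time constants must be positive")
    }
    if (tau1_range_s[1] < tau2_range_s[2]) {
      stop("tau1_range_s lower bound must be >= tau2_range_s upper bound, ",
           "so that tau1 > tau2 for every peak")
    }
    if (max(neutral_peaks_per_min) >= min(active_peaks_per_min)) {
      stop("neutral and active peak-count ranges must be disjoint ",
           "(max neutral < min active)")
    }
    if (min(neutral_peaks_per_min) < 0L) stop("peak counts must be >= 0")
    if (amplitude_range_uS[1] <= 0) stop("amplitudes must be positive")
    if (noise_sigma_uS < 0) stop("noise_sigma_uS must be nonnegative")
    if (min_peak_spacing_s < 0) stop("min_peak_spacing_s must be nonnegative")
    if (counts_per == "minute") {
      secs <- sequence_len_samples / sampling_rate_hz
      if (abs(secs / 60 - round(secs / 60)) > 1e-9 || secs < 60) {
        stop("with counts_per = \"minute\" the sequence must span a whole ",
             "number of minutes (got ", secs, " s)")
      }
    }
  })
  invisible(cfg)
}

#' @export
print.eda_sim_config <- function(x, ...) {
  cat("Synthetic EDA simulation configuration\n")
  cat(sprintf("  %g Hz, %d samples (%.1f min)\n", x$sampling_rate_hz,
              x$sequence_len_samples,
              x$sequence_len_samples / x$sampling_rate_hz / 60))
  cat(sprintf("  peaks per %s: neutral [%d, %d], active [%d, %d]\n",
              x$counts_per,
              x$neutral_peaks_per_min[1], x$neutral_peaks_per_min[2],
              x$active_peaks_per_min[1], x$active_peaks_per_min[2]))
  cat(sprintf("  tau1 (%g, %g) s, tau2 (%g, %g) s, amplitude (%g, %g) uS\n",
              x$tau1_range_s[1], x$tau1_range_s[2],
              x$tau2_range_s[1], x$tau2_range_s[2],
              x$amplitude_range_uS[1], x$amplitude_range_uS[2]))
  cat(sprintf("  baseline level (%g, %g) uS, noise sigma %g uS\n",
              x$baseline_level_range_uS[1], x$baseline_level_range_uS[2],
              x$noise_sigma_uS))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Number of whole minutes a configured sequence spans (>= 1 when counts are
# drawn per minute; for counts_per = "sequence" still used for reporting).
sim_minutes <- function(cfg) {
  cfg$sequence_len_samples / cfg$sampling_rate_hz / 60
}
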