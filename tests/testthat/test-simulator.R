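test_that("config validation enforces the generative invariants", {
  expect_s3_class(eda_sim_config(), "eda_sim_config")
  # overlapping count ranges
  expect_error(eda_sim_config(neutral_peaks_per_min = c(1, 6)), "disjoint")
  # tau ranges that would allow tau1 < tau2
  expect_error(eda_sim_config(tau1_range_s = c(0.5, 40)), "tau1")
  # per-minute counts need whole minutes
  expect_error(eda_sim_config(sequence_len_samples = 500), "whole")
  expect_s3_class(eda_sim_config(sequence_len_samples = 500,
                                 counts_per = "sequence"),
                  "eda_sim_config")
  expect_error(eda_sim_config(noise_sigma_uS = -1), "nonnegative")
})

test_that("peak counts are discrete-uniform in the label's range", {
  cfg <- short_config()
  set.seed(1)
  neutral <- replicate(1e4, draw_peak_counts(0, cfg))
  active <- replicate(100, draw_peak_counts(1, cfg))
  expect_true(all(neutral %in% 1:5))
  expect_true(all(active %in% 6:20))
  # closed-form mean of discrete uniform {1..5} is 3
  expect_equal(mean(neutral), 3, tolerance = 0.02)
  # degenerate range always yields its single value
  cfg_deg <- short_config(neutral_peaks_per_min = c(2, 2))
  expect_true(all(replicate(20, draw_peak_counts(0, cfg_deg)) == 2L))
  expect_error(draw_peak_counts(2, cfg), "label")
})

test_that("two-minute sequences draw one count per minute", {
  cfg <- eda_sim_config()
  set.seed(3)
  expect_length(draw_peak_counts(0, cfg), 2L)
  cfg_seq <- eda_sim_config(counts_per = "sequence")
  expect_length(draw_peak_counts(0, cfg_seq), 1L)
})

test_that("spike placement respects spacing and feasibility", {
  cfg <- short_config()
  set.seed(2)
  expect_length(place_spikes(c(0L), cfg)$onset_samples, 0L)
  cfg2 <- eda_sim_config()
  for (i in 1:20) {
    st <- place_spikes(c(5L, 5L), cfg2)
    expect_length(st$onset_samples, 10L)
    expect_true(all(diff(st$onset_samples) >= 5L))
    expect_true(all(st$onset_samples >= 0L &
                      st$onset_samples < cfg2$sequence_len_samples))
    expect_true(all(st$tau1_s > st$tau2_s))
    expect_true(all(st$tau2_s > 0))
    expect_true(all(st$amplitudes_uS > 0))
  }
  # 61 peaks with >= 5-sample gaps cannot fit in 300 samples
  expect_error(place_spikes(c(61L), cfg), "cannot place")
  expect_silent(invisible(place_spikes(c(60L), cfg)))
})

test_that("baseline is positive, slow, and constant when drift is off", {
  flat <- short_config(baseline_drift = list(
    slope_range_uS_per_min = c(0, 0), amp_range_uS = c(0, 0)))
  set.seed(4)
  b <- generate_baseline(flat)
  expect_equal(diff(range(b)), 0)
  expect_gte(b[1], flat$baseline_level_range_uS[1])
  cfg <- short_config()
  for (i in 1:300) {
    b <- generate_baseline(cfg)
    expect_true(all(b > 0))
    expect_lt(max(abs(diff(b))), 0.02)
  }
})

test_that("a lone spike peaks at its drawn amplitude", {
  cfg <- short_config(noise_sigma_uS = 0, baseline_drift = list(
    slope_range_uS_per_min = c(0, 0), amp_range_uS = c(0, 0)))
  spikes <- structure(list(onset_samples = 0L, amplitudes_uS = 0.8,
                           tau1_s = 2, tau2_s = 0.5),
                      class = "eda_spike_train")
  phasic <- edanet:::phasic_component(spikes, cfg)
  # unit-max kernel sampled at 5 Hz: peak within 1% of the amplitude
  expect_equal(max(phasic), 0.8, tolerance = 0.01)
  expect_identical(phasic[1], 0)
})

test_that("sequence decomposes exactly into its stored components", {
  cfg <- short_config()
  set.seed(5)
  for (label in c(0, 1)) {
    s <- generate_eda_sequence(label, cfg)
    phasic <- edanet:::phasic_component(s$spikes, cfg)
    expect_equal(s$values_uS, phasic + s$baseline_uS + s$noise_uS,
                 tolerance = 1e-12)
  }
})

test_that("noiseless sequence with no spikes equals its baseline", {
  cfg <- short_config(noise_sigma_uS = 0,
                      neutral_peaks_per_min = c(0L, 0L),
                      active_peaks_per_min = c(6L, 20L))
  set.seed(6)
  s <- generate_eda_sequence(0, cfg)
  expect_identical(s$values_uS, s$baseline_uS)
  expect_true(all(s$noise_uS == 0))
})

test_that("noiseless phasic component is nonnegative", {
  cfg <- short_config(noise_sigma_uS = 0)
  set.seed(7)
  for (i in 1:10) {
    s <- generate_eda_sequence(1, cfg)
    expect_true(all(s$values_uS - s$baseline_uS >= 0))
  }
})

test_that("doubling the amplitude range doubles the phasic part only", {
  base_drift <- list(slope_range_uS_per_min = c(0, 0), amp_range_uS = c(0, 0))
  cfg1 <- short_config(noise_sigma_uS = 0, baseline_drift = base_drift)
  cfg2 <- short_config(noise_sigma_uS = 0, baseline_drift = base_drift,
                       amplitude_range_uS = c(0.2, 2.0))
  set.seed(8)
  s1 <- generate_eda_sequence(1, cfg1)
  set.seed(8)
  s2 <- generate_eda_sequence(1, cfg2)
  expect_equal(s2$baseline_uS, s1$baseline_uS)
  expect_equal(s2$values_uS - s2$baseline_uS,
               2 * (s1$values_uS - s1$baseline_uS), tolerance = 1e-12)
})

test_that("two-minute ground-truth totals stay in the per-label ranges", {
  cfg <- eda_sim_config()
  set.seed(9)
  for (i in 1:10) {
    n0 <- length(generate_eda_sequence(0, cfg)$spikes$onset_samples)
    n1 <- length(generate_eda_sequence(1, cfg)$spikes$onset_samples)
    expect_true(n0 >= 2 && n0 <= 10)
    expect_true(n1 >= 12 && n1 <= 40)
  }
})

test_that("datasets are balanced, labeled, and seed-reproducible", {
  cfg <- short_config()
  ds <- generate_eda_dataset(11, cfg, balance = 0.5, seed = 10)
  expect_identical(dim(ds$sequences), c(11L, 300L))
  expect_identical(sum(ds$labels == 1L), 6L)  # round(11 * 0.5)
  ds2 <- generate_eda_dataset(11, cfg, balance = 0.5, seed = 10)
  expect_identical(ds, ds2)
  ds3 <- generate_eda_dataset(11, cfg, balance = 0.5, seed = 12)
  expect_false(identical(ds$sequences, ds3$sequences))
  expect_s3_class(generate_eda_dataset(1, cfg, seed = 1), "eda_dataset")
})

test_that("true peak rate separates the classes perfectly at 5.5/min", {
  cfg <- short_config()
  ds <- generate_eda_dataset(60, cfg, seed = 13)
  minutes <- cfg$sequence_len_samples / cfg$sampling_rate_hz / 60
  oracle <- as.integer(ds$spike_counts / minutes > 5.5)
  expect_identical(oracle, ds$labels)
})
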