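test_that("window count matches the closed formula and a brute-force walk", {
  set.seed(21)
  for (i in 1:100) {
    l <- sample(10:2000, 1)
    w <- sample(1:l, 1)
    s <- sample(1:500, 1)
    got <- nrow(segment_recording(seq_len(l), w, s))
    expect_identical(got, (l - w) %/% s + 1L)
    expect_identical(got, count_windows_brute(l, w, s))
  }
})

test_that("windows are exact half-open slices of the recording", {
  x <- seq_len(50)
  win <- segment_recording(x, 20, 10)
  expect_identical(nrow(win), 4L)
  for (k in seq_len(nrow(win))) {
    expect_identical(win[k, ], as.numeric(x[((k - 1) * 10 + 1):((k - 1) * 10 + 20)]))
  }
  # recording exactly one window long
  one <- segment_recording(x, 50, 25)
  expect_identical(nrow(one), 1L)
  expect_identical(one[1, ], as.numeric(x))
  # 700 samples, window 600, stride 300 -> a single window
  expect_identical(nrow(segment_recording(seq_len(700), 600, 300)), 1L)
})

test_that("a window longer than the recording warns and yields nothing", {
  expect_warning(win <- segment_recording(seq_len(10), 20, 5), "exceeds")
  expect_identical(nrow(win), 0L)
})

test_that("80 five-minute recordings at 5 Hz yield 320 overlapping windows", {
  recs <- lapply(1:80, function(i) {
    eda_recording(rep(5, 1500), 5, label = i %% 2, source_id = paste0("r", i))
  })
  ds <- segment_recordings(recs, 600, 300)
  expect_identical(nrow(ds$sequences), 320L)
  expect_identical(ds$provenance, "windowed-recording")
  # each window inherits its recording's label: 4 windows per recording
  expect_identical(ds$labels, rep(rep(c(1L, 0L), 40), each = 4))
})

test_that("z-scoring standardizes rows and maps constants to zero", {
  set.seed(22)
  x <- rbind(matrix(rnorm(5 * 60, mean = 4), 5, 60), rep(7, 60))
  z <- normalize_sequences(x, "zscore")
  for (i in 1:5) {
    expect_lt(abs(mean(z[i, ])), 1e-9)
    expect_lt(abs(sqrt(mean((z[i, ] - mean(z[i, ]))^2)) - 1), 1e-9)
  }
  expect_identical(z[6, ], rep(0, 60))
  expect_identical(normalize_sequences(x, "none"), x)
})

test_that("datasets survive a CSV + JSON round trip", {
  cfg <- short_config(seed = 23)
  ds <- generate_eda_dataset(3, cfg)
  base <- file.path(withr::local_tempdir(), "ds")
  save_eda_dataset(ds, base)
  expect_true(file.exists(paste0(base, ".csv")))
  back <- load_eda_dataset(base)
  expect_equal(back$sequences, ds$sequences, tolerance = 1e-8)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$provenance, ds$provenance)
  expect_identical(back$spike_counts, ds$spike_counts)
  expect_equal(back$config$active_peaks_per_min, ds$config$active_peaks_per_min)
  # 3 sequences -> 3 CSV rows x 300 columns
  raw <- utils::read.csv(paste0(base, ".csv"), header = FALSE)
  expect_identical(dim(raw), c(3L, 300L))
})

test_that("a sidecar with the wrong label count is rejected", {
  ds <- generate_eda_dataset(3, short_config(), seed = 24)
  base <- file.path(withr::local_tempdir(), "bad")
  save_eda_dataset(ds, base)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  meta$labels <- meta$labels[1:2]
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  expect_error(load_eda_dataset(base), "labels length")
})

test_that("recording CSVs load with or without a header", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "plain.csv")
  writeLines(c("2.5", "2.6", "2.7"), p1)
  r1 <- load_recording_csv(p1, 5, label = 1)
  expect_identical(r1$values_uS, c(2.5, 2.6, 2.7))
  expect_identical(r1$label, 1L)
  p2 <- file.path(dir, "header.csv")
  writeLines(c("conductance_uS", "3.1", "3.2"), p2)
  expect_identical(load_recording_csv(p2, 5)$values_uS, c(3.1, 3.2))
  p3 <- file.path(dir, "bad.csv")
  writeLines(c("1.0", "oops", "2.0"), p3)
  expect_error(load_recording_csv(p3, 5), "malformed")
})
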