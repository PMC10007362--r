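test_that("autoencoder training reduces reconstruction error", {
  set.seed(51)
  x <- matrix(rnorm(60 * 40), 60, 40) + sin(seq_len(40) / 3)
  ae <- train_autoencoder(x, hidden = 8, epochs = 30, seed = 1)
  expect_lt(tail(ae$history, 1), ae$history[1])
  rec <- predict(ae, x)
  expect_identical(dim(rec), dim(x))
})

test_that("constant-shape toy data reach near-zero reconstruction MAE", {
  # rows share one waveform; an identity-like mapping is representable
  base <- sin(seq_len(50) / 4)
  x <- t(replicate(40, base + rnorm(50, sd = 0.01)))
  ae <- train_autoencoder(x, hidden = 8, epochs = 200, lr = 5e-3, seed = 2)
  mae <- mae_per_sequence(ae, x)
  expect_true(all(mae >= 0))
  expect_lt(mean(mae), 0.2)  # on the z-scored scale (input sd is 1)
})

test_that("mixed-label datasets are refused", {
  ds <- generate_eda_dataset(6, short_config(), seed = 52)
  expect_error(train_autoencoder(ds), "neutral")
  neutral_only <- generate_eda_dataset(6, short_config(), balance = 0,
                                       seed = 52)
  expect_s3_class(train_autoencoder(neutral_only, hidden = 4, epochs = 2),
                  "eda_autoencoder")
})

test_that("identical MAE samples overlap completely and cannot be split", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  ov <- mae_overlap(a, a)
  expect_equal(ov$overlap_coefficient, 1)
  expect_equal(ov$balanced_accuracy, 0.5)
})

test_that("disjoint MAE supports give zero overlap and a perfect split", {
  set.seed(53)
  a <- runif(50, 0, 0.01)
  b <- runif(50, 0.1, 0.2)
  ov <- mae_overlap(a, b)
  expect_lt(ov$overlap_coefficient, 0.05)
  expect_equal(ov$balanced_accuracy, 1)
  expect_gt(ov$threshold, max(a))
  expect_lte(ov$threshold, min(b))
})

test_that("threshold sweep matches an exhaustive oracle on small inputs", {
  # oracle: evaluate balanced accuracy at every pooled value and +/- Inf
  oracle_best <- function(a, b) {
    cand <- c(-Inf, sort(unique(c(a, b))), Inf)
    best <- -1
    for (t in cand) {
      bal <- (mean(b >= t) + mean(a < t)) / 2
      if (bal > best) best <- bal
    }
    best
  }
  set.seed(54)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    a <- rgamma(n, 2, 20)
    b <- rgamma(n, sample(2:6, 1), 20)
    got <- mae_overlap(a, b)$balanced_accuracy
    expect_equal(got, oracle_best(a, b))
  }
})

test_that("the report is deterministic given the MAE lists", {
  set.seed(55)
  neutral <- generate_eda_dataset(30, short_config(), balance = 0, seed = 56)
  active <- generate_eda_dataset(30, short_config(), balance = 1, seed = 57)
  ae <- train_autoencoder(neutral, hidden = 8, epochs = 10, seed = 3)
  r1 <- ae_report(ae, neutral, active)
  r2 <- ae_report(ae, neutral, active)
  expect_identical(r1[c("overlap_coefficient", "suggested_threshold",
                        "threshold_accuracy")],
                   r2[c("overlap_coefficient", "suggested_threshold",
                        "threshold_accuracy")])
  expect_true(all(r1$mae_train >= 0))
  expect_gte(r1$overlap_coefficient, 0)
  expect_lte(r1$overlap_coefficient, 1)
})
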