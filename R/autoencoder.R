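#' Train an autoencoder on neutral sequences
#'
#' Reconstruction-error anomaly detection is the natural first attempt at
#' spotting active (stressed) windows without any stressed training data:
#' train an autoencoder on neutral sequences only and flag windows it
#' reconstructs poorly.  This module exists to demonstrate why that fails
#' for EDA -- neutral and active windows share the same waveform shape and
#' differ only in peak rate, so the reconstruction-error distributions
#' overlap.  The autoencoder is a dense encoder-decoder over the window
#' (input - tanh bottleneck - linear output) trained with minibatch Adam
#' on the mean squared error.
#'
#' @param x Numeric matrix of neutral sequences (rows) or an `eda_dataset`;
#'   a dataset containing any active label is refused.
#' @param hidden Bottleneck width.
#' @param epochs Training epochs.
#' @param lr Adam step size.
#' @param batch_size Minibatch size.
#' @param normalize `"zscore"` (per-sequence, default) or `"none"`;
#'   reconstruction errors are measured on this scale.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return An object of class `eda_autoencoder` with the weight matrices,
#'   the normalization mode and the per-epoch training MSE (`history`).
#' @examples
#' \donttest{
#' ds <- generate_eda_dataset(40, eda_sim_config(seed = 2), balance = 0)
#' ae <- train_autoencoder(ds, epochs = 20, seed = 1)
#' }
#' @export
train_autoencoder <- function(x, hidden = 32L, epochs = 100L, lr = 1e-3,
                              batch_size = 32L,
                              normalize = c("zscore", "none"),
                              seed = 1L, verbose = FALSE) {
  normalize <- match.arg(normalize)
  if (inherits(x, "eda_dataset")) {
    if (!is.null(x$labels) && any(x$labels != 0L)) {
      stop("the autoencoder is trained on neutral sequences only; ",
           "the dataset contains active labels")
    }
    x <- x$sequences
  }
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("no training sequences")
  if (normalize == "zscore") x <- zscore_rows(x)
  d <- ncol(x)
  h <- as.integer(hidden)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  W1 <- matrix(stats::rnorm(d * h, 0, sqrt(1 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * d, 0, sqrt(1 / h)), h, d)
  b2 <- numeric(d)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(p) p * 0)
  v <- m
  t_step <- 0
  history <- numeric(epochs)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(n, start + batch_size - 1L)]
      xb <- x[idx, , drop = FALSE]
      hid <- tanh(sweep(xb %*% params$W1, 2L, params$b1, "+"))
      rec <- sweep(hid %*% params$W2, 2L, params$b2, "+")
      err <- rec - xb
      loss <- mean(err^2)
      ep_loss <- ep_loss + loss * length(idx)
      drec <- 2 * err / length(err)
      g <- list(
        W1 = NULL, b1 = NULL,
        W2 = crossprod(hid, drec), b2 = colSums(drec)
      )
      dhid <- (drec %*% t(params$W2)) * (1 - hid^2)
      g$W1 <- crossprod(xb, dhid)
      g$b1 <- colSums(dhid)
      t_step <- t_step + 1
      b1c <- 1 - 0.9^t_step
      b2c <- 1 - 0.999^t_step
      for (nm in names(params)) {
        m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
        v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr * (m[[nm]] / b1c) / (sqrt(v[[nm]] / b2c) + 1e-8)
      }
    }
    history[ep] <- ep_loss / n
    if (verbose) cat(sprintf("epoch %d  mse %.6f\n", ep, history[ep]))
  }
  structure(list(
    W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
    hidden = h, input_len = d, normalize = normalize,
    history = history, seed = as.integer(seed)
  ), class = "eda_autoencoder")
}

#' @export
print.eda_autoencoder <- function(x, ...) {
  cat(sprintf(
    "Dense EDA autoencoder: %d -> %d -> %d, final training MSE %.5f\n",
    x$input_len, x$hidden, x$input_len, utils::tail(x$history, 1)))
  invisible(x)
}

#' Reconstruct sequences with a trained autoencoder
#'
#' @param object An `eda_autoencoder`.
#' @param newdata Matrix of sequences (rows) or an `eda_dataset`.
#' @param ... Unused.
#' @return Matrix of reconstructions, same shape as the (normalized) input.
#' @export
predict.eda_autoencoder <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "eda_dataset")) newdata$sequences else
    as.matrix(newdata)
  if (ncol(x) != object$input_len) {
    stop("sequences have ", ncol(x), " samples but the model expects ",
         object$input_len)
  }
  if (object$normalize == "zscore") x <- zscore_rows(x)
  hid <- tanh(sweep(x %*% object$W1, 2L, object$b1, "+"))
  sweep(hid %*% object$W2, 2L, object$b2, "+")
}

#' Per-sequence reconstruction mean absolute error
#'
#' @param model A trained `eda_autoencoder`.
#' @param sequences Matrix of sequences (rows) or an `eda_dataset`.
#' @return Numeric vector: `mean(|x - xhat|)` per sequence, on the model's
#'   input scale.
#' @export
mae_per_sequence <- function(model, sequences) {
  x <- if (inherits(sequences, "eda_dataset")) sequences$sequences else
    as.matrix(sequences)
  if (model$normalize == "zscore") x <- zscore_rows(x)
  rec <- predict(model, if (inherits(sequences, "eda_dataset"))
    sequences$sequences else sequences)
  rowMeans(abs(x - rec))
}

#' Overlap of two reconstruction-error distributions
#'
#' Measures how separable two sets of per-sequence MAE values are: the
#' overlap coefficient is the shared area of the two empirical densities
#' (histogram intersection on common Freedman-Diaconis bins; 1 = identical,
#' 0 = disjoint), and the best threshold is the MAE cut maximizing balanced
#' accuracy under the rule "MAE >= threshold is anomalous", found by brute
#' force over midpoints of the pooled sorted values.
#'
#' @param mae_a MAE values of the reference (neutral/training) class.
#' @param mae_b MAE values of the anomalous (active) class.
#' @return List with `overlap_coefficient`, `threshold` and
#'   `balanced_accuracy` at that threshold.
#' @examples
#' mae_overlap(c(1, 2, 3), c(10, 11, 12))  # disjoint: overlap 0, accuracy 1
#' @export
mae_overlap <- function(mae_a, mae_b) {
  a <- as.numeric(mae_a)
  b <- as.numeric(mae_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty MAE list")
  sweep_res <- threshold_sweep(a, b)
  list(overlap_coefficient = histogram_overlap(a, b),
       threshold = sweep_res$threshold,
       balanced_accuracy = sweep_res$balanced_accuracy)
}

# Shared area of two histograms on common Freedman-Diaconis bins.
histogram_overlap <- function(a, b) {
  pooled <- c(a, b)
  rng <- range(pooled)
  if (diff(rng) < .Machine$double.eps) return(1)
  bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  if (bw <= 0) bw <- diff(rng) / ceiling(sqrt(length(pooled)))
  breaks <- seq(rng[1], rng[2] + bw, by = bw)
  pa <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  pb <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}

# Brute-force threshold search over midpoints of the pooled sorted values
# (plus one cut below and one above everything); anomalous when MAE >= t.
threshold_sweep <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  cand <- c(pooled[1] - 1,
            if (length(pooled) > 1L) (pooled[-1] + pooled[-length(pooled)]) / 2,
            pooled[length(pooled)] + 1)
  best <- list(threshold = cand[1], balanced_accuracy = -1)
  for (t in cand) {
    bal <- (mean(b >= t) + mean(a < t)) / 2
    if (bal > best$balanced_accuracy + 1e-12) {
      best <- list(threshold = t, balanced_accuracy = bal)
    }
  }
  best
}

#' Autoencoder separability report
#'
#' Runs the full demonstration: reconstruction MAE on the neutral
#' (training-distribution) and active sets, their overlap coefficient, and
#' the best achievable thresholded balanced accuracy.
#'
#' @param model A trained `eda_autoencoder`.
#' @param neutral_sequences,active_sequences Matrices of sequences (rows)
#'   or `eda_dataset`s.
#' @return An object of class `ae_report` with `mae_train`,
#'   `mae_anomalous`, `overlap_coefficient`, `suggested_threshold` and
#'   `threshold_accuracy` (balanced accuracy at the suggested threshold).
#' @export
ae_report <- function(model, neutral_sequences, active_sequences) {
  mae_n <- mae_per_sequence(model, neutral_sequences)
  mae_a <- mae_per_sequence(model, active_sequences)
  ov <- mae_overlap(mae_n, mae_a)
  structure(list(
    mae_train = mae_n,
    mae_anomalous = mae_a,
    overlap_coefficient = ov$overlap_coefficient,
    suggested_threshold = ov$threshold,
    threshold_accuracy = ov$balanced_accuracy
  ), class = "ae_report")
}

#' @export
print.ae_report <- function(x, ...) {
  cat("Autoencoder reconstruction-error report\n")
  cat(sprintf("  neutral MAE: median %.4f (n = %d)\n",
              stats::median(x$mae_train), length(x$mae_train)))
  cat(sprintf("  active  MAE: median %.4f (n = %d)\n",
              stats::median(x$mae_anomalous), length(x$mae_anomalous)))
  cat(sprintf("  distribution overlap %.3f\n", x$overlap_coefficient))
  cat(sprintf("  best threshold %.4f -> balanced accuracy %.3f\n",
              x$suggested_threshold, x$threshold_accuracy))
  invisible(x)
}

#' Plot the two MAE distributions
#'
#' Overlaid histograms of the neutral and active reconstruction errors,
#' the visual form of the overlap diagnostic.
#'
#' @param x An `ae_report`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.ae_report <- function(x, ...) {
  pooled <- c(x$mae_train, x$mae_anomalous)
  breaks <- pretty(pooled, n = 30)
  hn <- graphics::hist(x$mae_train, breaks = breaks, plot = FALSE)
  ha <- graphics::hist(x$mae_anomalous, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(hn$counts, ha$counts))
  graphics::plot(hn, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, xlab = "reconstruction MAE",
                 main = "Neutral vs active reconstruction error", ...)
  graphics::plot(ha, col = grDevices::adjustcolor("firebrick", 0.5),
                 add = TRUE)
  graphics::abline(v = x$suggested_threshold, lty = 2)
  graphics::legend("topright", c("neutral", "active"),
                   fill = c(grDevices::adjustcolor("steelblue", 0.5),
                            grDevices::adjustcolor("firebrick", 0.5)),
                   bty = "n")
  invisible(x)
}
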