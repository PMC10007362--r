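#' Train the fully convolutional neutral/active classifier
#'
#' Fits the 1D FCN described by an [fcn_spec()] to labeled fixed-length
#' conductance sequences with minibatch Adam on the sparse categorical
#' cross-entropy, monitoring sparse categorical accuracy on a stratified
#' validation split (80/20 by default).  Early stopping keeps the weights
#' of the epoch with the best validation accuracy.  Sequences are
#' z-scored per sequence before entering the network (disable with
#' `normalize = "none"`).
#'
#' @param x An `eda_dataset` (labels taken from it) or a numeric matrix
#'   with one sequence per row.
#' @param y Integer 0/1 labels when `x` is a matrix.
#' @param spec An [fcn_spec()]; its `input_len` must match the data.
#' @param val_fraction Fraction held out for validation, in (0, 1).
#' @param lr Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement); `Inf` disables early stopping.
#' @param normalize `"zscore"` (default) or `"none"`.
#' @param seed Integer seed controlling the split, weight initialization
#'   and shuffling.
#' @param verbose Print per-epoch metrics.
#' @return An object of class `fcn_classifier` with elements `spec`,
#'   `weights`, `history` (data frame of per-epoch train/validation loss
#'   and accuracy), `best_epoch`, `normalize`, `n_train`, `n_val` and
#'   `seed`.
#' @examples
#' \donttest{
#' ds <- generate_eda_dataset(60, eda_sim_config(seed = 1))
#' fit <- fcn_train(ds, spec = fcn_spec(filters = 8), epochs = 2, seed = 1)
#' predict(fit, ds$sequences[1:3, ])
#' }
#' @export
fcn_train <- function(x, y = NULL, spec = fcn_spec(),
                      val_fraction = 0.2, lr = 1e-3, batch_size = 128L,
                      epochs = 50L, patience = 10L,
                      normalize = c("zscore", "none"),
                      seed = 1L, verbose = FALSE) {
  normalize <- match.arg(normalize)
  if (inherits(x, "eda_dataset")) {
    if (is.null(x$labels)) stop("dataset has no labels")
    y <- x$labels
    x <- x$sequences
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(inherits(spec, "fcn_spec"))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 (neutral) or 1 (active)")
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class; both neutral and active ",
         "sequences are required")
  }
  if (ncol(x) != spec$input_len) {
    stop("sequences have ", ncol(x), " samples but spec$input_len is ",
         spec$input_len)
  }
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must be in (0, 1)")
  }
  if (normalize == "zscore") x <- zscore_rows(x)

  split <- stratified_split(y, val_fraction, seed)
  w0 <- cpp_fcn_init(spec$in_channels, spec$filters, spec$kernel_width,
                     spec$n_blocks, spec$n_classes, as.integer(seed))
  fin_patience <- if (is.finite(patience)) as.integer(patience) else
    as.integer(epochs)
  fit <- cpp_fcn_train(w0,
                       x[split$train, , drop = FALSE], y[split$train],
                       x[split$val, , drop = FALSE], y[split$val],
                       lr, as.integer(batch_size), as.integer(epochs),
                       fin_patience, spec$dropout, as.integer(seed),
                       isTRUE(verbose))
  history <- as.data.frame(fit$history)
  names(history) <- c("epoch", "loss", "accuracy", "val_loss", "val_accuracy")
  structure(list(
    spec = spec,
    weights = fit$weights,
    history = history,
    best_epoch = fit$best_epoch,
    val_accuracy = fit$best_val_accuracy,
    normalize = normalize,
    n_train = length(split$train),
    n_val = length(split$val),
    seed = as.integer(seed),
    call = match.call()
  ), class = "fcn_classifier")
}

# Seeded stratified holdout: within each class, round(n_c * val_fraction)
# indices go to validation.
stratified_split <- function(y, val_fraction, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  val <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_val <- round(length(idx) * val_fraction)
    val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(y), val), val = val)
}

#' Predict labels or class probabilities
#'
#' @param object A fitted `fcn_classifier`.
#' @param newdata Numeric matrix of sequences (rows) or an `eda_dataset`.
#' @param type `"class"` for 0/1 labels, `"prob"` for the softmax matrix
#'   with columns `neutral` and `active`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Integer labels or a probability matrix whose rows sum to 1.
#' @export
predict.fcn_classifier <- function(object, newdata,
                                   type = c("class", "prob"),
                                   batch_size = 256L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "eda_dataset")) newdata$sequences else
    as.matrix(newdata)
  if (nrow(x) == 0L) {
    return(if (type == "class") integer(0) else
      matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("neutral", "active"))))
  }
  if (ncol(x) != object$spec$input_len) {
    stop("sequences have ", ncol(x), " samples but the model expects ",
         object$spec$input_len)
  }
  if (object$normalize == "zscore") x <- zscore_rows(x)
  p <- cpp_fcn_predict(object$weights, x, as.integer(batch_size))
  colnames(p) <- c("neutral", "active")
  if (type == "prob") p else as.integer(max.col(p) - 1L)
}

#' @export
print.fcn_classifier <- function(x, ...) {
  cat(sprintf(
    "Fully convolutional EDA classifier (%d blocks x %d filters, k = %d)\n",
    x$spec$n_blocks, x$spec$filters, x$spec$kernel_width))
  cat(sprintf("  trained on %d sequences (%d validation), %d epochs run\n",
              x$n_train, x$n_val, nrow(x$history)))
  cat(sprintf("  best validation accuracy %.4f at epoch %d\n",
              x$val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
summary.fcn_classifier <- function(object, ...) {
  print(object)
  cat("\nArchitecture:\n")
  print(fcn_layer_table(object$spec), row.names = FALSE)
  cat("\nTraining history (last epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Plot training history
#'
#' Train and validation accuracy (solid / dashed) against epoch, with loss
#' on a second panel.
#'
#' @param x A fitted `fcn_classifier`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fcn_classifier <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l",
                    lty = c(1, 2), col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = c(1, 2), col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  invisible(x)
}

#' Extract model weights
#'
#' @param object A fitted `fcn_classifier`.
#' @param ... Unused.
#' @return Nested list of conv/batch-norm/dense weight arrays.
#' @export
coef.fcn_classifier <- function(object, ...) object$weights

#' Save / load a fitted classifier as JSON
#'
#' All weight arrays (with their dimensions), the architecture spec, the
#' normalization mode and the training history are written to a single
#' JSON file, the package's serialized model format; loading reproduces a
#' `fcn_classifier` whose predictions match the original.
#'
#' @param object A fitted `fcn_classifier`.
#' @param path File path to write to / read from.
#' @return `save_fcn_classifier()` returns `path` invisibly;
#'   `load_fcn_classifier()` returns the `fcn_classifier`.
#' @export
save_fcn_classifier <- function(object, path) {
  stopifnot(inherits(object, "fcn_classifier"))
  ser <- function(a) list(dim = if (is.null(dim(a))) length(a) else dim(a),
                          values = as.numeric(a))
  payload <- list(
    format = "edanet-fcn-1",
    spec = unclass(object$spec),
    normalize = object$normalize,
    history = object$history,
    best_epoch = object$best_epoch,
    val_accuracy = object$val_accuracy,
    n_train = object$n_train,
    n_val = object$n_val,
    seed = object$seed,
    weights = list(
      # named (not array-valued) so JSON readers keep the structure intact
      blocks = stats::setNames(
        lapply(object$weights$blocks, function(b) lapply(b, ser)),
        paste0("block", seq_along(object$weights$blocks))),
      dense = lapply(object$weights$dense, ser)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fcn_classifier
#' @export
load_fcn_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "edanet-fcn-1")) {
    stop("not an edanet classifier file: ", path)
  }
  deser <- function(s) {
    if (length(s$dim) > 1L) array(s$values, dim = s$dim) else
      as.numeric(s$values)
  }
  spec <- do.call(fcn_spec, as.list(payload$spec))
  weights <- list(
    blocks = lapply(seq_len(spec$n_blocks), function(i) {
      b <- payload$weights$blocks[[i]]
      lapply(b, deser)
    }),
    dense = lapply(payload$weights$dense, deser)
  )
  weights$dense$W <- matrix(weights$dense$W, spec$n_classes, spec$filters)
  structure(list(
    spec = spec,
    weights = weights,
    history = as.data.frame(payload$history),
    best_epoch = payload$best_epoch,
    val_accuracy = payload$val_accuracy,
    normalize = payload$normalize,
    n_train = payload$n_train,
    n_val = payload$n_val,
    seed = payload$seed,
    call = NULL
  ), class = "fcn_classifier")
}

#' Audit the built model against the declared parameter counts
#'
#' Counts the actual number of parameters stored in each layer of a fitted
#' (or freshly initialized) model and compares with
#' [layer_parameter_count()].
#'
#' @param object A fitted `fcn_classifier` or an [fcn_spec()] (which is
#'   then initialized with `seed`).
#' @param seed Seed used when `object` is a spec.
#' @return The [fcn_layer_table()] with an extra column `params_built`
#'   counted from the weight arrays.
#' @export
fcn_parameter_audit <- function(object, seed = 1L) {
  if (inherits(object, "fcn_spec")) {
    spec <- object
    weights <- cpp_fcn_init(spec$in_channels, spec$filters, spec$kernel_width,
                            spec$n_blocks, spec$n_classes, as.integer(seed))
  } else {
    stopifnot(inherits(object, "fcn_classifier"))
    spec <- object$spec
    weights <- object$weights
  }
  tab <- fcn_layer_table(spec)
  built <- integer(nrow(tab))
  for (b in seq_len(spec$n_blocks)) {
    blk <- weights$blocks[[b]]
    built[tab$layer == paste0("conv1d_", b)] <-
      length(blk$W) + length(blk$b)
    built[tab$layer == paste0("batch_normalization_", b)] <-
      length(blk$gamma) + length(blk$beta) + length(blk$run_mean) +
      length(blk$run_var)
  }
  built[tab$layer == "dense"] <-
    length(weights$dense$W) + length(weights$dense$b)
  tab$params_built <- built
  tab
}
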