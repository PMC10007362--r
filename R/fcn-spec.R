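#' Architecture specification for the 1D fully convolutional classifier
#'
#' Describes the network applied to fixed-length conductance windows: a
#' stack of conv / batch-norm / ReLU blocks with same-padded width-3
#' convolutions (temporal length is preserved through every block),
#' followed by global average pooling over time and a dense softmax head.
#' The default spec -- three blocks of 64 filters on a 600-sample
#' single-channel input -- has per-layer parameter counts 256 (first conv),
#' 12,352 (later convs), 256 (each batch norm, counting the non-trainable
#' moving statistics) and 130 (dense head).
#'
#' @param input_len Input sequence length in samples.
#' @param in_channels Number of input channels (1 for raw conductance).
#' @param n_blocks Number of conv/batch-norm/ReLU blocks.
#' @param filters Filters per convolution.
#' @param kernel_width Convolution kernel width (odd, for same padding).
#' @param n_classes Number of output classes.
#' @param dropout Optional dropout rate applied after each block's ReLU
#'   during training (0 disables; the canonical architecture has none).
#' @return An object of class `fcn_spec`.
#' @examples
#' spec <- fcn_spec()
#' fcn_layer_table(spec)
#' @export
fcn_spec <- function(input_len = 600L, in_channels = 1L, n_blocks = 3L,
                     filters = 64L, kernel_width = 3L, n_classes = 2L,
                     dropout = 0) {
  spec <- structure(list(
    input_len = as.integer(input_len),
    in_channels = as.integer(in_channels),
    n_blocks = as.integer(n_blocks),
    filters = as.integer(filters),
    kernel_width = as.integer(kernel_width),
    n_classes = as.integer(n_classes),
    dropout = as.numeric(dropout)
  ), class = "fcn_spec")
  with(spec, {
    if (input_len < 1L) stop("input_len must be >= 1")
    if (in_channels < 1L) stop("in_channels must be >= 1")
    if (n_blocks < 1L) stop("n_blocks must be >= 1")
    if (filters < 1L) stop("filters must be >= 1")
    if (kernel_width < 1L || kernel_width %% 2L == 0L) {
      stop("kernel_width must be a positive odd integer (same padding)")
    }
    if (n_classes < 2L) stop("n_classes must be >= 2")
    if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  })
  spec
}

#' Per-layer summary of an FCN spec
#'
#' One row per layer in forward order (input, then conv / batch norm / ReLU
#' per block, then global average pooling and the dense softmax head), with
#' the output shape and the total parameter count of each layer.  Batch
#' norm counts include the two non-trainable moving statistics per channel,
#' so a 64-channel batch norm has `4 * 64 = 256` parameters.
#'
#' @param spec An [fcn_spec()].
#' @return Data frame with columns `layer`, `type`, `output_shape`,
#'   `params`.
#' @export
fcn_layer_table <- function(spec) {
  stopifnot(inherits(spec, "fcn_spec"))
  rows <- list(list(layer = "input", type = "InputLayer",
                    output_shape = shape_str(spec$input_len, spec$in_channels),
                    params = 0L))
  cin <- spec$in_channels
  for (b in seq_len(spec$n_blocks)) {
    conv_p <- spec$kernel_width * cin * spec$filters + spec$filters
    rows <- c(rows, list(
      list(layer = paste0("conv1d_", b), type = "Conv1D",
           output_shape = shape_str(spec$input_len, spec$filters),
           params = as.integer(conv_p)),
      list(layer = paste0("batch_normalization_", b),
           type = "BatchNormalization",
           output_shape = shape_str(spec$input_len, spec$filters),
           params = as.integer(4L * spec$filters)),
      list(layer = paste0("re_lu_", b), type = "ReLU",
           output_shape = shape_str(spec$input_len, spec$filters),
           params = 0L)))
    cin <- spec$filters
  }
  rows <- c(rows, list(
    list(layer = "global_average_pooling1d", type = "GlobalAveragePooling1D",
         output_shape = sprintf("(None, %d)", spec$filters), params = 0L),
    list(layer = "dense", type = "Dense",
         output_shape = sprintf("(None, %d)", spec$n_classes),
         params = as.integer(spec$filters * spec$n_classes + spec$n_classes))))
  do.call(rbind, lapply(rows, as.data.frame))
}

shape_str <- function(len, channels) sprintf("(None, %d, %d)", len, channels)

#' Parameter count of a single layer
#'
#' Counts follow the standard conventions: a convolution has
#' `kernel_width * in_channels * filters + filters` parameters, a batch
#' norm `4 * channels` (scale, shift, moving mean, moving variance), the
#' dense head `in * out + out`, and input / ReLU / pooling layers none.
#'
#' @param spec An [fcn_spec()].
#' @param layer_index 1-based index into the rows of [fcn_layer_table()].
#' @return Integer parameter count.
#' @examples
#' layer_parameter_count(fcn_spec(), 2)  # first convolution: 256
#' @export
layer_parameter_count <- function(spec, layer_index) {
  tab <- fcn_layer_table(spec)
  i <- as.integer(layer_index)
  if (i < 1L || i > nrow(tab)) {
    stop("layer_index must be in 1..", nrow(tab))
  }
  tab$params[i]
}

#' @export
print.fcn_spec <- function(x, ...) {
  tab <- fcn_layer_table(x)
  cat(sprintf(
    "FCN spec: %d x (Conv1D[%d, k=%d] + BatchNorm + ReLU) -> GAP -> Dense(%d)\n",
    x$n_blocks, x$filters, x$kernel_width, x$n_classes))
  if (x$dropout > 0) cat(sprintf("  dropout %.2f after each block\n", x$dropout))
  print(tab, row.names = FALSE)
  cat(sprintf("Total params: %s\n", format(sum(tab$params), big.mark = ",")))
  invisible(x)
}
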