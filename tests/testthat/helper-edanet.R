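# Shared fixtures: small configurations keep unit tests fast; acceptance
# checks use the full default configuration.

# One-minute sequences at the default 5 Hz.
short_config <- function(...) {
  eda_sim_config(sequence_len_samples = 300L, ...)
}

# Tiny architecture for fast training tests.
tiny_spec <- function(input_len = 60L, filters = 4L, n_blocks = 2L, ...) {
  fcn_spec(input_len = input_len, filters = filters, n_blocks = n_blocks, ...)
}

# Perfectly separable toy data: class 0 near 0, class 1 near 1.
toy_separable <- function(n = 40L, len = 60L, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(stats::rnorm(n * len, sd = 0.05), n, len) + y
  list(x = x, y = as.integer(y))
}

# Independent window-count oracle: walk the recording start by start.
count_windows_brute <- function(l, w, s) {
  n <- 0L
  start <- 1L
  while (start + w - 1L <= l) {
    n <- n + 1L
    start <- start + s
  }
  n
}
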