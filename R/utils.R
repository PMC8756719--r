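# Internal helpers shared across the package.

# Input/validation errors get a dedicated condition class so callers (and the
# command-line wrapper) can distinguish bad input from numerical failure.
stop_input <- function(..., call. = FALSE) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c("dnmap_input_error", "error")))
}

stop_numeric <- function(..., call. = FALSE) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c("dnmap_numeric_error", "error")))
}

# Deterministic batch index list: samples shuffled once per epoch, then cut
# into consecutive batches. Both AE pre-training and joint fine-tuning use
# this single helper so that, at lambda = 0, the two consume the RNG
# identically and take identical optimizer steps.
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
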