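# Internal helpers shared across modules.

# Deterministically fold an arbitrary stream of integers/strings into a single
# RNG seed strictly below 2^31, so every stochastic stage can derive an
# independent, reproducible sub-stream from one user-facing seed.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...), use.names = FALSE)
  codes <- unlist(lapply(parts, function(p) {
    if (is.character(p)) utf8ToInt(p) else as.integer(p)
  }))
  acc <- as.double(seed) %% 2147483629
  for (v in codes) {
    acc <- (acc * 69069 + as.double(v) + 1) %% 2147483629
  }
  as.integer(acc) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(msg) abort(msg, class = "presaboost_input_error")

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop_input(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}
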