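# shared internal helpers

# stop() with a consistent prefix-free classed error
stop_spatcube <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "spatcube_error")
}

assert_scalar_number <- function(x, name, positive = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_spatcube("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_spatcube("`%s` must be strictly positive", name)
  if (integerish && x != round(x)) stop_spatcube("`%s` must be a whole number", name)
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_spatcube(
      "%s is missing mandatory column(s): %s", what,
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

# run code under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL runs in the ambient stream
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# deterministic short hash (polynomial rolling hash over the deparsed object)
# used to tag runs; avoids an extra dependency and is stable across sessions
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
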