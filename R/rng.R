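# Deterministic substreams: every (message, m, purpose) combination gets its
# own seed derived from the run seed, so results never depend on the order in
# which messages are processed.

# 32-bit polynomial rolling hash of the string parts, folded with the base
# seed; always returns a non-negative integer < 2^31 - 1.
substream_seed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(parts)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a local RNG state seeded at `seed`; the caller's RNG state is
# untouched.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
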