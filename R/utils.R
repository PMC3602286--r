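#' @keywords internal
"_PACKAGE"

# Round half away from zero, the convention used for all printed percentages.
# Base round() uses banker's rounding, which would turn e.g. 26.05 into 26.0.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  force(code)
}

# Polynomial rolling hash of an R object's serialization, as 8 hex digits;
# used to stamp report headers so a rerun with identical configuration is
# recognizable. Not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (R-version-dependent fields sit in bytes 1-14)
  bytes <- bytes[-seq_len(14)]
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
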