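# Internal helpers: reproducible per-unit seeds and RNG scoping.

# Deterministic 31-bit seed from a master seed and a string key, so that
# per-community (or per-run) streams do not depend on processing order.
derive_seed <- function(master, key) {
  m <- 2147483563
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% m
  as.integer((as.numeric(master) %% m + h * 48271) %% m)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
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
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
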