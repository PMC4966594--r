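# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed stream: keeps values in [1, 2^31 - 2] so they are
# valid set.seed() inputs for any small integer base seed.
derive_seed <- function(base_seed, index) {
  base <- as.numeric(base_seed) %% 2147483647
  s <- (base * 48271 + as.numeric(index) * 104729) %% 2147483647
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Online process parameter column order used throughout.
ONLINE_VARS <- c("CER", "DO", "OUR", "pH", "SS", "Temp")
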