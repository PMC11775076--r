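# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs under the current RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed derived from a root seed and a label (an
# integer index or a character id). Keeps per-subject simulation reproducible
# independently of iteration order; result always in [0, 2^31 - 2].
derive_seed <- function(root, label) {
  root <- as.double(root %% 2147483647)
  if (is.character(label)) {
    h <- 0
    for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483647
  } else {
    h <- as.double(label) %% 2147483647
  }
  as.integer((root * 69621 + h * 48271 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccaf <- function(...) stop(..., call. = FALSE)

# single-row extraction that keeps a data.frame a list-like record
as_record <- function(df, i) as.list(df[i, , drop = FALSE])
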