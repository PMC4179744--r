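# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = use the
# current stream). The caller's .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) computed stably; optional log-weights lw of equal length.
logsumexp <- function(x, lw = NULL) {
  if (!is.null(lw)) x <- x + lw
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying within the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
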