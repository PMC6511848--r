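# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Canonicalize an unordered id pair: sorted, so (a,b) == (b,a).
canonical_pair <- function(a, b) {
  swap <- b < a
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  cbind(a, b, deparse.level = 0)
}

# Single string key per unordered pair, used for set membership tests.
pair_key <- function(a, b) {
  cp <- canonical_pair(as.character(a), as.character(b))
  paste(cp[, 1L], cp[, 2L], sep = "\r")
}

stop_input <- function(...) stop(..., call. = FALSE)
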