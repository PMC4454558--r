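#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic operations in the package
# funnel through this so they are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a sub-seed < 2^31 from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  # guard against floating-point spill just outside [-1, 1]
  clip(sum(a * b) / (na * nb), -1, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
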