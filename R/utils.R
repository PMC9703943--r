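# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (including exact equality, e.g. single-variant regions)
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic functions in the package route their randomness through
# this so that no global state leaks between calls.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# Shared tie-break ordering: ascending p, then descending |beta|, then
# lexicographic variant id. Returns an ordering permutation.
tie_order <- function(pval, beta, variant_id) {
  order(pval, -abs(beta), variant_id)
}

stop_ratiomr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ratiomr_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
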