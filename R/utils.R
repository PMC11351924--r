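# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-item sub-seed derived from a base seed; kept within
# 32-bit integer range.
derive_seed <- function(base, i) as.integer((as.numeric(base) * 7919 + i * 104729) %% 2147483647)
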