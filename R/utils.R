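# Internal helpers: scoped RNG control and deterministic sub-streams.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# A NULL seed leaves the global RNG stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds below 2^31, derived from a base seed: one
# session-level seed fans out into independent component seeds.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  as.integer((as.double(seed) %% m * 48271 + offset * 9973 + 1) %% m)
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
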