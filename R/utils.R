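# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
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

# Derive a stream-specific child seed, kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest absolute eigenvalue; guards the (I - M)^{-1} solve.
spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}
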