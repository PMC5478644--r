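# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps generator calls free of global
# side effects so seeded pipelines are reproducible in any order.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific 32-bit seed from a base seed without collisions
# between generator calls in the same pipeline run.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + stream * 40503) %% 2147483647)
}
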