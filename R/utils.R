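# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package functions never perturb the
# global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

# Derive a sub-seed from a master seed and a stream offset. Each operation of
# the package draws from its own derived stream so that adding or reordering
# operations does not shift the randomness of the others. Kept below 2^31-1.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + 12345 + offset * 2654435761) %% 2147483587) + 1L
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
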