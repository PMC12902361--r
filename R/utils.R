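# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-locus seed streams: the i-th locus seed is the i-th
# draw from a stream seeded by the master seed, so it depends only on the
# master seed and the locus index, never on how many loci are requested.
derive_seeds <- function(master_seed, n) {
  if (is.null(master_seed)) {
    return(sample.int(2147483646L, n))
  }
  with_seed(master_seed, sample.int(2147483646L, n))
}

stop_bad <- function(...) stop(..., call. = FALSE)

DNA_STATES <- c("A", "C", "G", "T")
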