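# Internal helpers: argument checks and RNG discipline.

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x == floor(x)

# Snapshot the full RNG state (.Random.seed encodes kind + state),
# initialising the RNG first if it has never been touched so that the kind
# can never leak through a missing seed.
rng_snapshot <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  get(".Random.seed", envir = globalenv())
}

rng_restore <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

# Run `expr` under a temporary seed (kind pinned for cross-session
# reproducibility), restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

# round-half-away-from-zero for non-negative panel fractions
round_half_up <- function(x) floor(x + 0.5)

# sample() resolves a length-1 vector as 1:x; this keeps set semantics
sample_from <- function(x, size) x[sample.int(length(x), size)]
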