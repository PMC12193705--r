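# Save/restore the global RNG state so seeded generators are pure functions of
# their seed and leave the caller's random stream untouched.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
.child_seeds <- function(seed, n) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
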