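#' @keywords internal
"_PACKAGE"

# Run code under a given RNG seed, restoring the caller's RNG state afterwards.
# All generators use this so that a fixed seed gives bit-identical output
# regardless of surrounding RNG usage.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from one root seed. Keeps results of different
# pipeline stages statistically independent while everything flows from a
# single integer. Always < 2^31.
derive_seed <- function(root, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
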