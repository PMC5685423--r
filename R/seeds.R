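#' Derive a child seed from a parent seed
#'
#' Deterministic integer seed stream used throughout the pipeline so that a
#' single master seed reproduces every subject, run, trial and frame. The
#' recurrence is a fixed-point LCG-style hash over the index path; it is not
#' cryptographic, only collision-sparse and reproducible across platforms.
#' Results stay below 2^31.
#'
#' @param seed parent integer seed.
#' @param ... one or more non-negative integer indices (e.g. subject, run,
#'   trial) identifying the child stream.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  s <- as.double(seed) %% 2147483563
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) %% 65536) * 1299721 + 12345) %% 2147483563
  }
  as.integer(s) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
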