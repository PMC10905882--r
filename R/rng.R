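# Seed plumbing: every stochastic operation takes one user-facing seed and
# derives independent child seeds for its internal stages, so pipelines are
# reproducible end to end while stages stay decoupled.

#' Derive a child seed from a root seed
#'
#' Deterministic integer mixing that keeps results inside the 32-bit
#' range R requires of `set.seed()`. Distinct `(seed, stream)` pairs map
#' to distinct child seeds with overwhelming probability.
#'
#' @param seed integer root seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  m <- 2147483629 # largest prime below 2^31
  x <- (as.double(seed) %% m)
  for (s in c(stream, 104729)) {
    x <- (x * 48271 + as.double(s) * 16807 + 12345) %% m
  }
  as.integer(x)
}

# Run code with a temporarily-set RNG state; NULL seed leaves the global
# stream untouched (caller inherits ambient randomness).
with_rng <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
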