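#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used to give every stochastic component
#' (fixtures, spike encoders, experiment draws) its own independent stream
#' from a single master seed. The result is always in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param stream Integer stream index (component identifier).
#' @return A single integer seed.
#' @export
child_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 48271 + as.numeric(stream) * 2246822519 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

# A self-contained uniform RNG stream: rng <- rng_stream(seed, k); rng(n)
# returns the next n U(0,1) variates. The stream keeps its own RNG state and
# always restores the caller's .Random.seed, so library code never perturbs
# user-level randomness.
rng_stream <- function(master, stream = 0L) {
  seed <- child_seed(master, stream)
  state <- NULL
  function(k) {
    genv <- globalenv()
    had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had_old) get(".Random.seed", envir = genv) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = genv)
    out <- stats::runif(k)
    state <<- get(".Random.seed", envir = genv)
    if (had_old) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
    out
  }
}
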