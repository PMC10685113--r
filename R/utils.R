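# Internal: an isolated RNG stream.
#
# Generators must be pure functions of their seed and must not disturb the
# caller's global RNG state, so each stream stashes and restores
# .Random.seed around every draw.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())

  draw <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    pois = function(n, lambda) draw(function() stats::rpois(n, lambda)),
    sample_int = function(n, size, replace = FALSE)
      draw(function() sample.int(n, size, replace = replace))
  )
}

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
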