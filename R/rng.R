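# Self-contained random stream. Every stochastic operation in the package
# draws from one of these, so a seed fully determines all synthetic data and
# the caller's global .Random.seed is left untouched.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(
    runif = function(...) run(stats::runif, ...),
    rnorm = function(...) run(stats::rnorm, ...),
    sample_int = function(n, size = n, replace = FALSE, prob = NULL)
      run(sample.int, n, size, replace, prob),
    # derive a child seed (< 2^31) for nested generators
    child_seed = function() run(sample.int, .Machine$integer.max, 1))
}
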