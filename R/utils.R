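# Seed-handling helpers. All randomized operations in the package draw from
# a private RNG stream seeded explicitly, leaving the caller's global
# .Random.seed untouched.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# a resumable uniform RNG stream under its own seed
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- .withSeed(seed, get(".Random.seed", globalenv()))
  function(n) {
    had <- exists(".Random.seed", globalenv())
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
    x
  }
}
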