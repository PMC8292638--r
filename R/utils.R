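# shared numeric helpers

# population standard deviation (divisor N), matching numpy.std's default,
# which is what the trajectory features were originally computed with
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# z-score with population SD
pop_z <- function(x) {
  s <- pop_sd(x)
  if (s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# restore the caller-visible RNG state after seeded internal sampling
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
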