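# Seeded evaluation that restores the caller's RNG state afterwards.
with_test_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_image <- function(n = 64L, seed = 3L) {
  with_test_seed(seed, matrix(runif(n * n), n, n))
}
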