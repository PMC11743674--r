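# Run code under a temporary RNG state so generators and initialisers are
# reproducible without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a child seed, kept inside the 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289L) %% 2147483629)
}
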