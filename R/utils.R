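# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# sin(x)/x with the removable singularity at 0 defined as 1
.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

# fixed 8-significant-digit formatting used by all ASCII writers, so that
# write -> read -> write round-trips byte-identically
.fmt <- function(x) sprintf("%.8g", x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
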