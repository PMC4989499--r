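# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# stop() without the call, with sprintf-style formatting
cw_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Full-precision numeric formatting for text output (round-trips doubles).
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  int <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[int] <- sprintf("%.0f", x[int])
  out
}
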