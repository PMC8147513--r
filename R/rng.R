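#' Derive a reproducible child seed from a session seed and a stream name
#'
#' All randomness in a session flows from a single integer seed through named
#' child streams (one per measurement, preference query, hyperparameter
#' restart, ...), so each component is independently reproducible and the
#' whole session is bit-reproducible on a given platform.
#'
#' @param seed integer master seed.
#' @param stream character stream label, e.g. `"measure/3"`.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
child_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    invalid_parameter("`seed` must be a single finite number")
  m <- 2147483647  # 2^31 - 1, keeps derived seeds inside R's integer range
  h <- 0
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + code) %% m
  }
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
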