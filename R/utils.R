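#' @keywords internal
"_PACKAGE"

# Wrap an angle (radians) to (-pi, pi].
wrap_pi <- function(a) {
  b <- a %% (2 * pi)
  ifelse(b > pi, b - 2 * pi, b)
}

# Wrap an axis angle (defined modulo pi) to (-pi/2, pi/2].
wrap_half_pi <- function(a) {
  b <- a %% pi
  ifelse(b > pi / 2, b - pi, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic per-frame seed derived from a scene seed; stays < 2^31.
frame_seed <- function(seed, t) {
  (as.numeric(seed) * 7919 + as.numeric(t) * 104729) %% 2147483647
}

# Evaluate expr with a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
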