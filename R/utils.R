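`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards.  All stochastic operations in the package
## go through this so no function mutates global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and an index, kept inside the
## 32-bit signed integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

deg2rad <- function(x) x * pi / 180

## 2x2 rotation matrix acting on image coordinates (x right, y down).
## A positive angle rotates the +x axis towards +y.
rot2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}
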