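#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generator functions route through this
# so that identical (config, seed) pairs give bit-identical output without
# clobbering the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# log(sum(exp(x))) without overflow; used by the colocalization enumeration.
logsum <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamps tiny negative round-off to -Inf.
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dtmr <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_dtmr(msg, ...)
  invisible(TRUE)
}
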