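#' @keywords internal
#' @importFrom stats rnorm sd cor median var qf pf plogis lm coef resid fft
#'   setNames runif sample.int
#' @importFrom utils write.csv head packageVersion
"_PACKAGE"

# Round half away from zero (display pipelines round 127.5 -> 128, unlike
# base::round's banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the global RNG with `seed`, evaluates `expr`, and restores the
#' previous RNG state, so package randomness never disturbs a caller's
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation: a small multiplicative hash over the
# base seed and any number of string/numeric tokens, reduced modulo a prime
# below 2^31 so the result is always a valid R integer seed.
child_seed <- function(base_seed, ...) {
  p <- 2147483587
  h <- as.numeric(base_seed) %% p
  for (tok in list(...)) {
    bytes <- if (is.character(tok)) utf8ToInt(paste(tok, collapse = "|"))
             else round_half_up(as.numeric(tok) * 1000)
    for (b in bytes) h <- (h * 131 + (as.numeric(b) %% p) + 7) %% p
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
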