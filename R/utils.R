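## Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the
#' convention used in the package's summary tables), unlike base
#' \code{round()} which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(c(0.25, -0.25), 1)  # 0.3, -0.3
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic generators route through this.
withSeed <- function(seed, expr) {
  seed <- asSeed(seed)
  withr::with_seed(seed, expr)
}

asSeed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}

## Derive a sub-seed for stage `k` from a master seed; keeps independent
## streams reproducible while staying within 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(asSeed(seed)) * 48271 + k) %% 2147483647)
}

checkPositiveCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

checkNonNegativeCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

## Stop with an error object carrying a subclass so pipeline code can flag
## individual cells instead of aborting a whole run.
stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
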