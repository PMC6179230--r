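#' Derive a reproducible sub-seed from a master seed
#'
#' Generators and simulation harnesses in this package take a single master
#' seed and derive independent sub-seeds for each team, repeat or stream, so
#' that any single unit can be regenerated in isolation. The derivation is a
#' fixed affine hash modulo a Mersenne prime, keeping results inside the
#' 32-bit integer range `set.seed()` accepts.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483629
  as.integer(((abs(master) %% 65521) * 32749 + (stream %% m) * 7919 + 1) %% m)
}

#' Clip values into an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values forced into `[lo, hi]`.
#' @keywords internal
clip01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

## population standard deviation (divide by n); the convention used for all
## per-team descriptive features extracted from networks and chat logs
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
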