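#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow/underflow; used everywhere a
#' posterior normalisation or mixture is formed in log space.
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return a single numeric value; `-Inf` for an empty or all-`-Inf` input.
#' @export
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a per-task seed from a master seed
#'
#' Counter-based splitting: the seed for task `index` depends only on
#' `(master, index)`, so adding grid cells or replicates never perturbs the
#' seeds of existing ones. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index non-negative integer task counter.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) + 1
  # two rounds of a multiplicative congruential mix keyed by the counter
  s <- (s * 48271 + as.numeric(index) * 69621 + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s + (s == 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
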