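#' @importFrom stats plnorm qlnorm pnorm qnorm runif rnorm rlnorm setNames
#' @importFrom stats aggregate complete.cases
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Sample from a lognormal distribution truncated to [lo, hi]
#'
#' Inverse-CDF sampling: uniforms are drawn on the CDF interval
#' corresponding to the truncation bounds, so every draw respects them
#' exactly.
#'
#' @param n number of draws.
#' @param meanlog,sdlog log-scale parameters.
#' @param lo,hi truncation bounds (kg in the weight-per-fish use).
#' @return numeric vector of length `n` in `[lo, hi]`.
#' @export
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  if (lo >= hi) stop("truncation bounds require lo < hi", call. = FALSE)
  if (sdlog == 0) {
    w <- exp(meanlog)
    if (w < lo || w > hi) {
      stop("degenerate distribution mass lies outside the truncation bounds",
           call. = FALSE)
    }
    return(rep(w, n))
  }
  p_lo <- plnorm(lo, meanlog, sdlog)
  p_hi <- plnorm(hi, meanlog, sdlog)
  if (p_hi - p_lo <= 0) stop("no mass inside the truncation bounds", call. = FALSE)
  qlnorm(runif(n, p_lo, p_hi), meanlog, sdlog)
}

#' Mean of a truncated lognormal distribution (closed form)
#'
#' E[X | lo <= X <= hi] for X ~ lognormal(meanlog, sdlog), from the
#' partial-expectation identity of the lognormal.
#'
#' @inheritParams rlnorm_trunc
#' @return the truncated mean (scalar).
#' @export
lnorm_trunc_mean <- function(meanlog, sdlog, lo, hi) {
  if (sdlog == 0) return(exp(meanlog))
  a <- (log(lo) - meanlog) / sdlog
  b <- (log(hi) - meanlog) / sdlog
  num <- pnorm(b - sdlog) - pnorm(a - sdlog)
  den <- pnorm(b) - pnorm(a)
  exp(meanlog + sdlog^2 / 2) * num / den
}

# Truncated geometric on 1..max_k with success probability p: the count
# distribution for fish per landing record, favouring single-fish landings.
rgeom_trunc <- function(n, p, max_k) {
  probs <- p * (1 - p)^(0:(max_k - 1))
  probs <- probs / sum(probs)
  sample.int(max_k, n, replace = TRUE, prob = probs)
}

# Fold an angular difference into [0, 180] degrees.
fold_angle <- function(delta) {
  abs(((delta + 180) %% 360) - 180)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
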