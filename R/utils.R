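# Small numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(exp(a) + exp(b))
#' @param a,b numeric vectors (recycled).
#' @return numeric vector.
#' @keywords internal
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # both -Inf -> -Inf (m - m is NaN there)
  out[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- -Inf
  out
}

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

#' Truncated normal density
#'
#' Density of a normal distribution with location \code{mean} and scale
#' \code{sd}, truncated to \code{(lower, upper)} and renormalized by the
#' truncation mass.
#'
#' @param x quantiles.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds (may be infinite).
#' @param log if TRUE return the log density.
#' @return density values; 0 (or -Inf) outside the support.
#' @export
dtnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf, log = FALSE) {
  stopifnot(sd > 0, lower < upper)
  lz <- log(pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
  ld <- dnorm(x, mean, sd, log = TRUE) - lz
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' Truncated normal random draws
#'
#' Inverse-CDF sampler for the truncated normal. Adequate for the moderate
#' truncations used here (zero-bounded with location within a few scales of
#' the bound).
#'
#' @param n number of draws.
#' @inheritParams dtnorm
#' @return numeric vector of draws inside (lower, upper).
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  u <- runif(n, pl, pu)
  # clamp away from 0/1 so qnorm stays finite
  u <- pmin(pmax(u, .Machine$double.xmin), 1 - .Machine$double.eps)
  qnorm(u, mean, sd)
}

#' Mean of a truncated normal (closed form)
#' @inheritParams dtnorm
#' @keywords internal
tnorm_mean <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Evaluate a log-density function on a matrix of draws (rows) or a single
# vector; always returns a numeric vector.
eval_logq <- function(log_q, x) {
  if (is.matrix(x)) {
    out <- log_q(x)
    if (length(out) != nrow(x)) stop("log_q must return one value per row")
    out
  } else {
    log_q(matrix(x, nrow = 1))
  }
}

# Wrap a vector->scalar log density so it maps matrix rows to a vector.
rowwise_logq <- function(f) {
  function(x) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    vapply(seq_len(nrow(x)), function(i) f(x[i, ]), numeric(1))
  }
}
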