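# Convergence diagnostics: split-chain potential scale reduction and
# autocorrelation-based effective sample size.

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting every chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param samples an [lba_samples()] object, or a matrix
#'   (iterations x chains) for a single parameter.
#' @return named vector of R-hat values (one per parameter), or a scalar for
#'   a matrix input.
#' @export
rhat <- function(samples) {
  if (inherits(samples, "lba_samples")) {
    out <- vapply(seq_along(samples$pars), function(j)
      rhat(t(samples$draws[, , j])), numeric(1))
    names(out) <- samples$pars
    return(out)
  }
  x <- as.matrix(samples)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 iterations per chain for split R-hat")
  half <- n %/% 2
  x <- cbind(x[seq_len(half), , drop = FALSE],
             x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x); n <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted count of independent-equivalent draws, using
#' Geyer's initial monotone positive sequence per chain and summing across
#' chains.
#'
#' @param x a numeric vector (one chain), a matrix (iterations x chains), or
#'   an [lba_samples()] object (returns one ESS per parameter).
#' @return effective sample size(s), in (0, total draws].
#' @export
ess <- function(x) {
  if (inherits(x, "lba_samples")) {
    out <- vapply(seq_along(x$pars), function(j) ess(t(x$draws[, , j])),
                  numeric(1))
    names(out) <- x$pars
    return(out)
  }
  if (is.matrix(x)) return(sum(apply(x, 2, ess_chain)))
  ess_chain(as.numeric(x))
}

ess_chain <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(1)
  max_lag <- min(n - 2, 10 * floor(sqrt(n)))
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  # Geyer: sum pairs Gamma_k = rho_{2k} + rho_{2k+1} while positive,
  # enforcing monotone decrease
  npair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g < 0) break
    g <- min(g, prev)
    tau <- tau + 2 * g
    prev <- g
  }
  max(min(n / tau, n), 1)
}
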