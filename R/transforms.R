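# Componentwise transformations of bounded parameters to the real line,
# their inverses, and log-Jacobian adjustments.  Warping assumes samples
# range over the whole real line, so bounded parameters are mapped before
# the proposal moments are fitted:
#   lower-bounded:  omega = log(theta - l)
#   upper-bounded:  omega = log(u - theta)
#   double-bounded: omega = qnorm((theta - l) / (u - l))
# The transformed-scale un-normalized posterior is the natural-scale one
# plus log|d theta / d omega|.

#' Classify a parameter's bounds
#'
#' @param lower,upper scalar bounds, lower < upper, possibly infinite.
#' @return one of \code{"unbounded"}, \code{"lower"}, \code{"upper"},
#'   \code{"double"}.
#' @export
classify_bounds <- function(lower, upper) {
  if (!(lower < upper)) stop("need lower < upper")
  lf <- is.finite(lower); uf <- is.finite(upper)
  if (lf && uf) "double" else if (lf) "lower" else if (uf) "upper"
  else "unbounded"
}

#' Transform a parameter to the real line
#'
#' @param theta values strictly inside (lower, upper); vectorized.
#' @param lower,upper scalar bounds.
#' @return unbounded values omega.
#' @export
to_real <- function(theta, lower = -Inf, upper = Inf) {
  type <- classify_bounds(lower, upper)
  if (type != "unbounded" && any(theta <= lower | theta >= upper))
    stop("theta on or outside a finite bound")
  switch(type,
         unbounded = theta,
         lower = log(theta - lower),
         upper = log(upper - theta),
         double = qnorm((theta - lower) / (upper - lower)))
}

#' Back-transform from the real line
#'
#' Inverse of [to_real()]; accepts any real omega.
#'
#' @param omega real values; vectorized.
#' @inheritParams to_real
#' @export
from_real <- function(omega, lower = -Inf, upper = Inf) {
  switch(classify_bounds(lower, upper),
         unbounded = omega,
         lower = exp(omega) + lower,
         upper = upper - exp(omega),
         double = (upper - lower) * pnorm(omega) + lower)
}

#' Log Jacobian of the back-transformation
#'
#' log |d theta / d omega| evaluated at omega: 0 for unbounded, omega for
#' one-sided bounds, log(u - l) + log phi(omega) for double bounds.  This is
#' the term added to the natural-scale log posterior to obtain the
#' transformed-scale log posterior.
#'
#' @inheritParams from_real
#' @export
log_jacobian <- function(omega, lower = -Inf, upper = Inf) {
  switch(classify_bounds(lower, upper),
         unbounded = rep(0, length(omega)),
         lower = omega,
         upper = omega,
         double = log(upper - lower) + dnorm(omega, log = TRUE))
}

#' Transform a matrix of posterior draws to the real line
#'
#' Applies [to_real()] column by column and accumulates the per-draw
#' additive log-Jacobian.
#'
#' @param draws numeric matrix (draws x parameters).
#' @param bounds list with \code{lower} and \code{upper} vectors, one entry
#'   per column (recycled scalars allowed).
#' @return list with \code{omega} (matrix) and \code{log_jac} (vector): add
#'   \code{log_jac} to the natural-scale log q of each draw to obtain the
#'   transformed-scale log q.
#' @export
transform_samples <- function(draws, bounds) {
  stopifnot(is.matrix(draws))
  d <- ncol(draws)
  lo <- rep_len(bounds$lower, d); up <- rep_len(bounds$upper, d)
  omega <- draws
  log_jac <- numeric(nrow(draws))
  for (j in seq_len(d)) {
    bad <- which(is.finite(lo[j]) & draws[, j] <= lo[j] |
                   is.finite(up[j]) & draws[, j] >= up[j])
    if (length(bad))
      stop(sprintf("draw %d of parameter %s touches a bound", bad[1],
                   colnames(draws)[j] %||% j))
    omega[, j] <- to_real(draws[, j], lo[j], up[j])
    log_jac <- log_jac + log_jacobian(omega[, j], lo[j], up[j])
  }
  list(omega = omega, log_jac = log_jac)
}

# Back-transform a matrix of real-line draws; inverse of transform_samples.
untransform_samples <- function(omega, bounds) {
  d <- ncol(omega)
  lo <- rep_len(bounds$lower, d); up <- rep_len(bounds$upper, d)
  out <- omega
  for (j in seq_len(d)) out[, j] <- from_real(omega[, j], lo[j], up[j])
  out
}

# Row-wise log-Jacobian for a matrix of real-line draws.
log_jacobian_rows <- function(omega, bounds) {
  d <- ncol(omega)
  lo <- rep_len(bounds$lower, d); up <- rep_len(bounds$upper, d)
  lj <- numeric(nrow(omega))
  for (j in seq_len(d)) lj <- lj + log_jacobian(omega[, j], lo[j], up[j])
  lj
}
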