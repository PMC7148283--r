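# Linear ballistic accumulator: single-accumulator finishing-time
# distributions, defective race density, likelihood, and trial simulator.
#
# Each accumulator starts at a point drawn uniformly on (0, A), accumulates
# evidence at a rate drawn from a normal(v, s^2) truncated below at zero, and
# finishes when it reaches threshold b = A + B.  The observed response is the
# winning accumulator and RT = t0 + winning finishing time.

check_acc <- function(A, b, v, s) {
  if (any(!is.finite(c(A, b, s))) || s <= 0 || A < 0 || b < A)
    stop("invalid accumulator parameters: need s > 0, A >= 0, b >= A")
  if (pnorm(v / s) <= 0)
    stop("invalid accumulator parameters: truncation mass pnorm(v/s) is zero")
  invisible(TRUE)
}

#' Finishing-time CDF of a single LBA accumulator
#'
#' Distribution function of the time for one accumulator (uniform start on
#' (0, A), normal rate with mean \code{v} and SD \code{s} truncated below at
#' zero, threshold \code{b}) to reach threshold.  Because negative rates are
#' excluded by the truncation, the accumulator always finishes and the CDF
#' tends to 1.
#'
#' @param t decision time in seconds (vectorized); values <= 0 give 0.
#' @param A start-point range (evidence units).
#' @param b response threshold (evidence units), b >= A.
#' @param v mean drift rate (evidence/sec).
#' @param s drift-rate standard deviation (evidence/sec).
#' @return vector of probabilities between 0 and 1.
#' @export
lba_cdf <- function(t, A, b, v, s = 1) {
  check_acc(A, b, v, s)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  trunc_mass <- pnorm(v / s)
  if (A < 1e-6) {
    # deterministic start point: T = b / rate, rate ~ N(v, s^2) truncated > 0
    f <- pnorm((v - b / tp) / s) / trunc_mass
  } else {
    ts <- tp * s
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    f <- (1 +
            ((b - A - tp * v) / A) * pnorm(z1) -
            ((b - tp * v) / A) * pnorm(z2) +
            (ts / A) * (dnorm(z1) - dnorm(z2))) / trunc_mass
  }
  out[pos] <- pmin(pmax(f, 0), 1)
  out
}

#' Finishing-time density of a single LBA accumulator
#'
#' Density companion of [lba_cdf()]; integrates to 1 over (0, Inf).
#'
#' @inheritParams lba_cdf
#' @return vector of densities (per second), >= 0.
#' @export
lba_pdf <- function(t, A, b, v, s = 1) {
  check_acc(A, b, v, s)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  trunc_mass <- pnorm(v / s)
  if (A < 1e-6) {
    f <- (b / (tp^2 * s)) * dnorm((b / tp - v) / s) / trunc_mass
  } else {
    ts <- tp * s
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    f <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) /
      (A * trunc_mass)
  }
  out[pos] <- pmax(f, 0)
  out
}

#' Race parameter container
#'
#' Bundles the non-decision time and one accumulator parameter set per
#' response option.
#'
#' @param t0 non-decision time in seconds, > 0.
#' @param accumulators named list (one element per response label), each a
#'   list with components \code{A}, \code{b}, \code{v}, \code{s}.
#' @return an object of class \code{"lba_race"}.
#' @export
race_params <- function(t0, accumulators) {
  stopifnot(is.numeric(t0), t0 > 0, length(accumulators) >= 2)
  labs <- names(accumulators)
  if (is.null(labs) || anyDuplicated(labs))
    stop("accumulators must be uniquely named by response label")
  for (a in accumulators) check_acc(a$A, a$b, a$v, a$s)
  structure(list(t0 = t0, accumulators = accumulators), class = "lba_race")
}

#' Defective log density of (response, RT) under an LBA race
#'
#' Log of the winner's finishing-time density times the survival functions of
#' the losing accumulators, evaluated at decision time rt - t0.  Returns -Inf
#' for rt <= t0 (a structural zero); otherwise the per-trial density is
#' floored at exp(-700) so that extreme but legal observations do not
#' propagate -Inf through a likelihood sum.
#'
#' @param rt response times in seconds (vectorized).
#' @param response a single response label naming the winning accumulator.
#' @param race an [race_params()] object.
#' @return vector of log densities.
#' @export
dlba_race <- function(rt, response, race) {
  stopifnot(inherits(race, "lba_race"))
  labs <- names(race$accumulators)
  if (!response %in% labs) stop("unknown response label: ", response)
  td <- rt - race$t0
  w <- race$accumulators[[response]]
  ll <- log(lba_pdf(td, w$A, w$b, w$v, w$s))
  for (lab in setdiff(labs, response)) {
    a <- race$accumulators[[lab]]
    ll <- ll + log(pmax(1 - lba_cdf(td, a$A, a$b, a$v, a$s), 0))
  }
  out <- pmax(ll, -700)
  out[td <= 0] <- -Inf
  out
}

#' Log likelihood of a trial table
#'
#' Sums the defective log density over trials, where each trial's race
#' parameters are produced by a resolver function.  An empty table has log
#' likelihood 0.  Trials are grouped by (condition, stimulus) so the resolver
#' is called once per design cell.
#'
#' @param trials a trial data frame with columns
#'   \code{subject, condition, stimulus, response, rt}.
#' @param resolver function(condition, stimulus) returning an
#'   [race_params()] object.
#' @return scalar log likelihood; -Inf propagates.
#' @export
lba_loglik <- function(trials, resolver) {
  validate_trials(trials, require_rows = FALSE)
  if (nrow(trials) == 0) return(0)
  total <- 0
  cells <- unique(trials[, c("condition", "stimulus")])
  for (i in seq_len(nrow(cells))) {
    sel <- trials$condition == cells$condition[i] &
      trials$stimulus == cells$stimulus[i]
    race <- resolver(cells$condition[i], cells$stimulus[i])
    for (resp in unique(trials$response[sel])) {
      rsel <- sel & trials$response == resp
      total <- total + sum(dlba_race(trials$rt[rsel], resp, race))
      if (!is.finite(total)) return(-Inf)
    }
  }
  total
}

validate_trials <- function(trials, require_rows = TRUE) {
  need <- c("subject", "condition", "stimulus", "response", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (require_rows && nrow(trials) == 0) stop("trial table is empty")
  if (nrow(trials) && any(trials$rt <= 0)) stop("all rt must be > 0")
  invisible(TRUE)
}

#' Simulate trials from an LBA race
#'
#' Draws, per trial and accumulator, a start point uniform on (0, A) and a
#' rate from a normal(v, s^2) truncated below at zero; the finishing time is
#' (b - start)/rate, the winner is the minimum, and RT = t0 + winning time.
#'
#' @param race an [race_params()] object.
#' @param n number of trials (>= 0).
#' @param subject,condition,stimulus labels stamped onto the output rows.
#' @return a trial data frame (see [lba_loglik()]).
#' @export
simulate_race <- function(race, n, subject = "s1", condition = "1",
                          stimulus = "s1") {
  stopifnot(inherits(race, "lba_race"), n >= 0)
  labs <- names(race$accumulators)
  if (n == 0)
    return(data.frame(subject = character(), condition = character(),
                      stimulus = character(), response = character(),
                      rt = numeric(), stringsAsFactors = FALSE))
  ft <- matrix(NA_real_, n, length(labs))
  for (j in seq_along(labs)) {
    a <- race$accumulators[[j]]
    start <- runif(n, 0, a$A)
    rate <- rtnorm(n, a$v, a$s, lower = 0)
    ft[, j] <- (a$b - start) / rate
  }
  win <- max.col(-ft)
  data.frame(subject = subject, condition = condition, stimulus = stimulus,
             response = labs[win], rt = race$t0 + ft[cbind(seq_len(n), win)],
             stringsAsFactors = FALSE)
}
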