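# Declarative LBA model designs and priors.
#
# A design maps a named parameter vector theta (plus constants) to the race
# parameters of every (condition x stimulus) cell: the accumulator matching
# the stimulus receives (v_true, s_true), the mismatching one (v_false,
# s_false), and b = A + B.  One parameter may vary by condition
# (condition_effect), giving the V- and B-models; "none" gives the 0-model.

#' Construct an LBA design
#'
#' @param name model label.
#' @param pars character vector of free parameter names.  Condition-indexed
#'   parameters are written \code{"v_true.1"}, \code{"v_true.2"} etc.
#' @param constants named numeric vector of fixed parameters (e.g.
#'   \code{c(s_true = 1)}).
#' @param condition_effect which base parameter varies across conditions
#'   (\code{"none"}, \code{"v_true"} or \code{"B"}).
#' @param conditions,stimuli,responses label sets; stimulus i is matched by
#'   response i.
#' @param prior a prior table, see [prior_spec()]; may be NULL for designs
#'   used only inside hierarchical models.
#' @return an object of class \code{"lba_design"}.
#' @export
lba_design <- function(name, pars, constants = c(s_true = 1, s_false = 1),
                       condition_effect = "none",
                       conditions = "1", stimuli = c("s1", "s2"),
                       responses = c("r1", "r2"), prior = NULL) {
  stopifnot(length(stimuli) == length(responses))
  base <- c("A", "B", "v_true", "v_false", "s_true", "s_false", "t0")
  for (p in base) {
    src <- if (condition_effect == p) paste0(p, ".", conditions) else p
    ok <- src %in% pars | src %in% names(constants)
    if (!all(ok))
      stop("parameter ", paste(src[!ok], collapse = ", "),
           " resolves to neither a free parameter nor a constant")
  }
  structure(list(name = name, pars = pars, constants = constants,
                 condition_effect = condition_effect,
                 conditions = as.character(conditions),
                 stimuli = stimuli, responses = responses,
                 match = stats::setNames(responses, stimuli),
                 prior = prior),
            class = "lba_design")
}

param_value <- function(design, theta, par, condition) {
  key <- if (identical(design$condition_effect, par))
    paste0(par, ".", condition) else par
  if (key %in% names(design$constants)) return(unname(design$constants[[key]]))
  if (!key %in% names(theta)) stop("cannot resolve parameter ", key)
  unname(theta[[key]])
}

#' Resolve a design cell to race parameters
#'
#' @param design an [lba_design()].
#' @param theta named parameter vector.
#' @param condition,stimulus cell labels.
#' @return an [race_params()] object.
#' @export
resolve_design <- function(design, theta, condition, stimulus) {
  stopifnot(inherits(design, "lba_design"))
  condition <- as.character(condition)
  if (!condition %in% design$conditions) stop("unknown condition: ", condition)
  if (!stimulus %in% design$stimuli) stop("unknown stimulus: ", stimulus)
  gv <- function(p) param_value(design, theta, p, condition)
  A <- gv("A"); b <- A + gv("B"); t0 <- gv("t0")
  accs <- lapply(design$responses, function(r) {
    role <- if (design$match[[stimulus]] == r) "true" else "false"
    list(A = A, b = b, v = gv(paste0("v_", role)), s = gv(paste0("s_", role)))
  })
  names(accs) <- design$responses
  race_params(t0, accs)
}

# ---- fast likelihood path -------------------------------------------------
# Pre-group a trial table once so that repeated likelihood evaluations (as in
# MCMC) avoid data-frame subsetting and race-object construction.

compile_trials <- function(design, trials) {
  validate_trials(trials, require_rows = FALSE)
  bad <- !trials$response %in% design$responses
  if (any(bad)) stop("unknown response label in trials: ",
                     paste(unique(trials$response[bad]), collapse = ", "))
  # per group, resolve each needed quantity to either an index into the
  # named parameter vector (slot) or a constant, so repeated likelihood
  # evaluations avoid any name lookups
  slot_of <- function(p, cond) {
    key <- if (identical(design$condition_effect, p)) paste0(p, ".", cond)
    else p
    if (key %in% names(design$constants))
      list(idx = NA_integer_, const = unname(design$constants[[key]]))
    else {
      i <- match(key, design$pars)
      if (is.na(i)) stop("cannot resolve parameter ", key)
      list(idx = i, const = NA_real_)
    }
  }
  groups <- list()
  for (cond in design$conditions) for (st in design$stimuli)
    for (resp in design$responses) {
      sel <- trials$condition == cond & trials$stimulus == st &
        trials$response == resp
      if (!any(sel)) next
      role <- if (design$match[[st]] == resp) "true" else "false"
      loser_role <- if (role == "true") "false" else "true"
      quant <- c("A", "B", "t0", paste0(c("v_", "s_"), role),
                 paste0(c("v_", "s_"), loser_role))
      slots <- lapply(quant, slot_of, cond = cond)
      groups[[length(groups) + 1L]] <-
        list(rt = trials$rt[sel], condition = cond,
             win = role, lose = loser_role,
             idx = vapply(slots, `[[`, integer(1), "idx"),
             const = vapply(slots, `[[`, numeric(1), "const"))
    }
  groups
}

# Unvalidated scalar-parameter kernels (validation happens once per call of
# the user-facing wrappers).
node_cdf_raw <- function(t, A, b, v, s) {
  trunc_mass <- pnorm(v / s)
  if (A < 1e-6) return(pmin(pmax(pnorm((v - b / t) / s) / trunc_mass, 0), 1))
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  f <- (1 + ((b - A - t * v) / A) * pnorm(z1) - ((b - t * v) / A) * pnorm(z2) +
          (ts / A) * (dnorm(z1) - dnorm(z2))) / trunc_mass
  pmin(pmax(f, 0), 1)
}

node_pdf_raw <- function(t, A, b, v, s) {
  trunc_mass <- pnorm(v / s)
  if (A < 1e-6) return(pmax((b / (t^2 * s)) * dnorm((b / t - v) / s), 0) / trunc_mass)
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  pmax((-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) /
         (A * trunc_mass), 0)
}

loglik_compiled <- function(design, compiled, theta) {
  # a bare numeric vector is taken to be in design$pars order
  if (!is.null(names(theta))) theta <- theta[design$pars]
  theta <- as.numeric(theta)
  total <- 0
  for (g in compiled) {
    p <- ifelse(is.na(g$idx), g$const, theta[g$idx])
    # order fixed by compile_trials: A, B, t0, v_win, s_win, v_lose, s_lose
    A <- p[1]; b <- A + p[2]; t0 <- p[3]
    vw <- p[4]; sw <- p[5]; vl <- p[6]; sl <- p[7]
    if (A < 0 || b < A || sw <= 0 || sl <= 0) return(-Inf)
    td <- g$rt - t0
    if (any(td <= 0)) return(-Inf)
    if (pnorm(vw / sw) <= 0 || pnorm(vl / sl) <= 0) return(-Inf)
    ll <- log(node_pdf_raw(td, A, b, vw, sw)) +
      log(pmax(1 - node_cdf_raw(td, A, b, vl, sl), 0))
    total <- total + sum(pmax(ll, -700))
  }
  total
}

#' Log likelihood of a trial table under a design
#'
#' Convenience wrapper around [lba_loglik()] that resolves race parameters
#' from a design and named parameter vector.
#'
#' @inheritParams resolve_design
#' @param trials a trial data frame.
#' @return scalar log likelihood.
#' @export
design_loglik <- function(design, theta, trials) {
  loglik_compiled(design, compile_trials(design, trials), theta)
}

# ---- priors ---------------------------------------------------------------

#' Prior specification table
#'
#' Independent (truncated) normal priors, one row per free parameter.
#'
#' @param par parameter names.
#' @param mean,sd locations and scales of the untruncated normals.
#' @param lower,upper truncation bounds (infinite allowed).
#' @return a data frame of class \code{"lba_prior"}.
#' @export
prior_spec <- function(par, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(all(sd > 0), all(lower < upper))
  structure(data.frame(par = par, mean = mean, sd = sd,
                       lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("lba_prior", "data.frame"))
}

#' Default single-participant priors
#'
#' A, B are zero-bounded normals N+(1, 1); v_true ~ N(2, 3^2) and
#' v_false ~ N(1, 3^2) are unbounded; t0 ~ N(0.3, 0.25^2) truncated below at
#' 0.1 s.
#'
#' @param pars which parameters to include (defaults to the full model).
#' @return an [prior_spec()] table.
#' @export
default_prior_single <- function(pars = c("A", "B", "v_true", "v_false", "t0")) {
  tab <- prior_spec(
    par   = c("A", "B", "v_true", "v_false", "t0"),
    mean  = c(1, 1, 2, 1, 0.3),
    sd    = c(1, 1, 3, 3, 0.25),
    lower = c(0, 0, -Inf, -Inf, 0.1),
    upper = Inf)
  out <- tab[match(pars, tab$par), , drop = FALSE]
  if (anyNA(out$par)) stop("no default prior for: ",
                           paste(pars[is.na(out$par)], collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("lba_prior", "data.frame")
  out
}

#' Log prior density
#'
#' Sum of independent truncated-normal log densities, each normalized by its
#' truncation mass; -Inf outside the support.
#'
#' @param theta named parameter vector (order must carry names matching the
#'   prior table).
#' @param prior an [prior_spec()] table.
#' @return scalar log density.
#' @export
log_prior <- function(theta, prior) {
  stopifnot(inherits(prior, "lba_prior"))
  x <- theta[prior$par]
  if (anyNA(x)) stop("theta is missing parameters named in the prior")
  sum(dtnorm(as.numeric(x), prior$mean, prior$sd, prior$lower, prior$upper,
             log = TRUE))
}

#' Sample from the prior
#'
#' @param prior an [prior_spec()] table (proper priors only).
#' @param n number of draws.
#' @return an n x p matrix with parameter-named columns.
#' @export
sample_prior <- function(prior, n = 1) {
  stopifnot(inherits(prior, "lba_prior"), n >= 1)
  if (any(!is.finite(prior$mean)) || any(!is.finite(prior$sd)))
    stop("improper prior: unsupported")
  out <- vapply(seq_len(nrow(prior)), function(i)
    rtnorm(n, prior$mean[i], prior$sd[i], prior$lower[i], prior$upper[i]),
    numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, prior$par))
  out
}

#' Parameter bounds implied by a prior table
#'
#' @param prior an [prior_spec()] table.
#' @return list with named \code{lower} and \code{upper} vectors, the support
#'   used when transforming posterior samples to the real line.
#' @export
prior_bounds <- function(prior) {
  list(lower = stats::setNames(prior$lower, prior$par),
       upper = stats::setNames(prior$upper, prior$par))
}

# ---- single-participant posterior ----------------------------------------

#' Un-normalized log posterior for a single participant
#'
#' Returns a function that evaluates log likelihood + log prior on the
#' natural scale for one row of parameters at a time, or for a matrix of
#' rows.  The trial table is compiled once.
#'
#' @param design an [lba_design()] with a non-NULL prior.
#' @param trials a trial data frame.
#' @return function(matrix or named vector) -> numeric vector of log
#'   posterior values; -Inf outside the prior support.
#' @export
log_posterior_single <- function(design, trials) {
  stopifnot(inherits(design, "lba_design"), !is.null(design$prior))
  compiled <- compile_trials(design, trials)
  prior <- design$prior
  pars <- prior$par
  stopifnot(identical(pars, design$pars))
  # precompute log truncation masses so the prior costs one dnorm per draw
  lz <- log(pnorm(prior$upper, prior$mean, prior$sd) -
              pnorm(prior$lower, prior$mean, prior$sd))
  pm <- prior$mean; ps <- prior$sd; pl <- prior$lower; pu <- prior$upper
  function(x) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    if (is.null(colnames(x))) colnames(x) <- pars
    reorder <- !identical(colnames(x), pars)
    vapply(seq_len(nrow(x)), function(i) {
      th <- x[i, ]
      if (reorder) th <- th[pars]
      thn <- as.numeric(th)
      if (any(thn <= pl) || any(thn >= pu)) return(-Inf)
      lp <- sum(dnorm(thn, pm, ps, log = TRUE) - lz)
      lp + loglik_compiled(design, compiled, thn)
    }, numeric(1))
  }
}

# ---- canonical study designs ---------------------------------------------

#' Single-participant study designs
#'
#' The full model has free A, B, v_true, v_false, t0 with both drift-rate SDs
#' fixed to 1; the restricted model additionally fixes v_true (default 3.55)
#' and drops its prior.
#'
#' @param model \code{"full"} or \code{"restricted"}.
#' @param v_true_fixed the fixed mean drift of the restricted model.
#' @return an [lba_design()] with its default prior attached.
#' @export
single_design <- function(model = c("full", "restricted"), v_true_fixed = 3.55) {
  model <- match.arg(model)
  if (model == "full")
    lba_design("full", pars = c("A", "B", "v_true", "v_false", "t0"),
               prior = default_prior_single())
  else
    lba_design("restricted", pars = c("A", "B", "v_false", "t0"),
               constants = c(s_true = 1, s_false = 1, v_true = v_true_fixed),
               prior = default_prior_single(c("A", "B", "v_false", "t0")))
}

#' Simulate a single-participant dataset from a design
#'
#' @param design an [lba_design()].
#' @param theta named generating parameter vector.
#' @param n_per_stimulus trials per (condition x stimulus) cell.
#' @param subject subject label.
#' @return a trial data frame with \code{n_per_stimulus *} cells rows.
#' @export
simulate_design <- function(design, theta, n_per_stimulus, subject = "s1") {
  out <- list()
  for (cond in design$conditions) for (st in design$stimuli) {
    race <- resolve_design(design, theta, cond, st)
    out[[length(out) + 1L]] <-
      simulate_race(race, n_per_stimulus, subject = subject,
                    condition = cond, stimulus = st)
  }
  do.call(rbind, out)
}

#' Generating parameter values for the single-participant study
#' @return named numeric vector.
#' @export
study1_generating_values <- function() {
  c(A = 0.5, B = 1, v_true = 4, v_false = 3, t0 = 0.2)
}
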