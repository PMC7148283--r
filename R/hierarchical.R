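# Hierarchical LBA models: participant-level parameters are drawn from
# independent zero-bounded normal group-level distributions with location
# mu_p and scale sigma_p; (mu_p, sigma_p) carry zero-bounded normal
# hyperpriors.  Participants are independent given the group level.

hyper_table <- function() {
  data.frame(par = c("A", "B", "v_true", "v_false", "s_false", "t0"),
             mean = c(1, 0.4, 3, 1, 1, 0.3),
             sd   = c(1, 0.4, 3, 1, 1, 0.3),
             stringsAsFactors = FALSE)
}

base_par <- function(p) sub("\\.[0-9]+$", "", p)

#' Hierarchical LBA model designs
#'
#' The V-model lets the matching mean drift rate differ across the two
#' conditions, the B-model the threshold gap, and the 0-model neither.  The
#' restricted B-model (\code{"B_res"}) is the B-model with the group-level
#' location of v_false fixed to 1.24 (no prior on it).  The matching
#' drift-rate SD s_true is fixed to 1 for every participant; s_false is a
#' free participant-level parameter.
#'
#' @param model one of \code{"V"}, \code{"0"}, \code{"B"}, \code{"B_res"}.
#' @return an object of class \code{"lba_hier"} with the trial-level design,
#'   the participant-level parameter list, the hyperprior table, and any
#'   fixed group-level locations.
#' @export
hier_design <- function(model = c("V", "0", "B", "B_res")) {
  model <- match.arg(model)
  eff <- switch(model, V = "v_true", `0` = "none", B = "B", B_res = "B")
  pp <- switch(model,
               V = c("A", "B", "v_true.1", "v_true.2", "v_false", "s_false", "t0"),
               `0` = c("A", "B", "v_true", "v_false", "s_false", "t0"),
               c("A", "B.1", "B.2", "v_true", "v_false", "s_false", "t0"))
  design <- lba_design(model, pars = pp, constants = c(s_true = 1),
                       condition_effect = eff, conditions = c("1", "2"))
  ht <- hyper_table()
  hyper <- ht[match(base_par(pp), ht$par), ]
  hyper$par <- pp
  rownames(hyper) <- NULL
  group_fixed <- if (model == "B_res") c(v_false = 1.24) else numeric(0)
  structure(list(name = model, design = design, pp = pp, hyper = hyper,
                 group_fixed = group_fixed),
            class = "lba_hier")
}

#' Group-level generating locations for the hierarchical studies
#'
#' @param model hierarchical model label.
#' @return named numeric vector of group-level locations mu_p; generating
#'   scales default to mu_p / 10.
#' @export
study2_generating_values <- function(model = c("V", "0", "B")) {
  model <- match.arg(model)
  switch(model,
         V = c(A = 1, B = 0.4, v_true.1 = 4, v_true.2 = 3, v_false = 1,
               s_false = 1, t0 = 0.3),
         `0` = c(A = 1, B = 0.4, v_true = 3, v_false = 1, s_false = 1,
                 t0 = 0.3),
         B = c(A = 1, B.1 = 0.3, B.2 = 0.7, v_true = 3.5, v_false = 1,
               s_false = 1, t0 = 0.3))
}

#' Generate a hierarchical dataset
#'
#' Draws participant-level parameters from zero-bounded normals with the
#' given group locations and scales (scales default to locations / 10) and
#' simulates k trials per (condition x stimulus) cell per participant.
#'
#' @param hier an [hier_design()].
#' @param n number of participants (>= 1).
#' @param k trials per design cell per participant (>= 1).
#' @param mu named group-level locations (defaults to the study generating
#'   values for the model).
#' @param sigma named group-level scales (defaults to mu / 10).
#' @return list with \code{trials}, the true participant parameter matrix
#'   \code{theta} (n x p), and \code{mu}, \code{sigma}.
#' @export
generate_hier_dataset <- function(hier, n, k, mu = NULL, sigma = NULL) {
  stopifnot(inherits(hier, "lba_hier"), n >= 1, k >= 1)
  mu <- mu %||% study2_generating_values(hier$name)
  mu <- mu[hier$pp]
  sigma <- sigma %||% (mu / 10)
  sigma <- stats::setNames(rep_len(sigma, length(mu)), hier$pp)
  p <- length(hier$pp)
  theta <- matrix(NA_real_, n, p, dimnames = list(NULL, hier$pp))
  subjects <- sprintf("p%02d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      th <- vapply(seq_len(p), function(j)
        if (sigma[j] > 0) rtnorm(1, mu[j], sigma[j], lower = 0) else mu[j],
        numeric(1))
      names(th) <- hier$pp
      if (all(th > 0) || any(sigma == 0)) break
    }
    theta[i, ] <- th
    out[[i]] <- simulate_design(hier$design, th, k, subject = subjects[i])
  }
  list(trials = do.call(rbind, out), theta = theta, mu = mu, sigma = sigma)
}

# group parameter vector layout: mu|<par> for free locations, sigma|<par>
# for every participant-level parameter
group_par_names <- function(hier) {
  free_mu <- setdiff(hier$pp, names(hier$group_fixed))
  c(paste0("mu|", free_mu), paste0("sigma|", hier$pp))
}

# expand a group vector to full (mu, sigma) including fixed locations
expand_group <- function(hier, g) {
  free_mu <- setdiff(hier$pp, names(hier$group_fixed))
  mu <- stats::setNames(numeric(length(hier$pp)), hier$pp)
  mu[free_mu] <- g[seq_along(free_mu)]
  if (length(hier$group_fixed)) mu[names(hier$group_fixed)] <- hier$group_fixed
  sigma <- g[length(free_mu) + seq_along(hier$pp)]
  names(sigma) <- hier$pp
  list(mu = mu, sigma = sigma)
}

# log hyperprior of a group vector (free mu first, then all sigma)
log_hyperprior <- function(hier, g) {
  eg <- expand_group(hier, g)
  free_mu <- setdiff(hier$pp, names(hier$group_fixed))
  h <- hier$hyper
  lm <- sum(dtnorm(eg$mu[free_mu], h$mean[match(free_mu, h$par)],
                   h$sd[match(free_mu, h$par)], 0, Inf, log = TRUE))
  ls <- sum(dtnorm(eg$sigma, h$mean, h$sd, 0, Inf, log = TRUE))
  lm + ls
}

# group-level log density of one participant-parameter matrix (n x p) under
# (mu, sigma); returns per-participant vector
group_logdens <- function(theta, mu, sigma) {
  if (any(sigma <= 0)) return(rep(-Inf, nrow(theta)))
  colSums(dtnorm(t(theta), mu, sigma, 0, Inf, log = TRUE))
}

compile_by_subject <- function(hier, trials) {
  subjects <- unique(trials$subject)
  lapply(stats::setNames(subjects, subjects), function(s)
    compile_trials(hier$design, trials[trials$subject == s, , drop = FALSE]))
}

#' Un-normalized hierarchical log posterior
#'
#' Sum of the per-participant log likelihoods, the group-level truncated
#' normal log densities of the participant parameters, and the hyperprior.
#'
#' @param hier an [hier_design()].
#' @param trials trial table covering all subjects.
#' @return function over the flattened parameter vector (participant blocks
#'   in subject order, then the group block; see \code{\link{hier_par_names}}),
#'   mapping a matrix of rows to a vector of log posterior values.
#' @export
log_posterior_hier <- function(hier, trials) {
  compiled <- compile_by_subject(hier, trials)
  n <- length(compiled)
  p <- length(hier$pp)
  gq <- length(group_par_names(hier))
  design <- hier$design
  function(x) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    stopifnot(ncol(x) == n * p + gq)
    vapply(seq_len(nrow(x)), function(r) {
      th <- matrix(x[r, seq_len(n * p)], n, p, byrow = TRUE,
                   dimnames = list(NULL, hier$pp))
      g <- x[r, n * p + seq_len(gq)]
      if (any(th <= 0) || any(g <= 0)) return(-Inf)
      lh <- log_hyperprior(hier, g)
      if (!is.finite(lh)) return(-Inf)
      eg <- expand_group(hier, g)
      gd <- sum(group_logdens(th, eg$mu, eg$sigma))
      if (!is.finite(gd)) return(-Inf)
      ll <- 0
      for (i in seq_len(n)) {
        ll <- ll + loglik_compiled(design, compiled[[i]], th[i, ])
        if (!is.finite(ll)) return(-Inf)
      }
      ll + gd + lh
    }, numeric(1))
  }
}

#' Flattened hierarchical parameter names
#'
#' @param hier an [hier_design()].
#' @param subjects subject labels in the order used by the sampler.
#' @return character vector: \code{"<par>|<subject>"} blocks followed by
#'   \code{"mu|<par>"} and \code{"sigma|<par>"}.
#' @export
hier_par_names <- function(hier, subjects) {
  c(as.vector(vapply(subjects, function(s) paste0(hier$pp, "|", s),
                     character(length(hier$pp)))),
    group_par_names(hier))
}

#' Bounds for the flattened hierarchical parameter vector
#'
#' All participant-level parameters and both group-level parameter types are
#' positive (zero-bounded group distributions and hyperpriors), so every
#' component is lower-bounded at zero.
#'
#' @inheritParams hier_par_names
#' @return list with \code{lower} and \code{upper} vectors.
#' @export
hier_bounds <- function(hier, subjects) {
  nm <- hier_par_names(hier, subjects)
  list(lower = stats::setNames(rep(0, length(nm)), nm),
       upper = stats::setNames(rep(Inf, length(nm)), nm))
}

#' Run the blocked hierarchical DE-MCMC sampler
#'
#' Chains number three times the participant-level parameter count.  Each
#' iteration updates every participant's block by crossover conditional on
#' that chain's current group parameters, then the group block conditional
#' on the participant parameters (a cheap update: no likelihood
#' evaluations).  Burn-in adds migration over full chain states and unstuck
#' replacement; the sampling phase is crossover-only with thinning.
#'
#' @param hier an [hier_design()].
#' @param trials trial table covering all subjects.
#' @param config a [de_config()]; \code{n_chains = NULL} means 3x the
#'   participant-level parameter count.
#' @param seed optional integer seed.
#' @return an [lba_samples()] object over the flattened parameter vector
#'   (see [hier_par_names()]), with split R-hat per parameter.
#' @export
run_de_mcmc_hier <- function(hier, trials, config = de_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  compiled <- compile_by_subject(hier, trials)
  subjects <- names(compiled)
  n <- length(subjects)
  p <- length(hier$pp)
  gq <- length(group_par_names(hier))
  nc <- config$n_chains %||% max(3 * p, 4)
  gamma_p <- config$gamma %||% (2.38 / sqrt(2 * p))
  gamma_g <- config$gamma %||% (2.38 / sqrt(2 * gq))
  design <- hier$design
  h <- hier$hyper

  # --- initialization: group from hyperprior, participants from the group
  theta <- array(NA_real_, c(nc, n, p))
  G <- matrix(NA_real_, nc, gq)
  ll <- matrix(-Inf, nc, n)   # per-subject log likelihood
  gd <- matrix(-Inf, nc, n)   # per-subject group-level log density
  hp <- rep(-Inf, nc)         # hyperprior
  free_mu <- setdiff(hier$pp, names(hier$group_fixed))
  for (c_ in seq_len(nc)) {
    for (try in 1:100) {
      gmu <- rtnorm(length(free_mu), h$mean[match(free_mu, h$par)],
                    h$sd[match(free_mu, h$par)], lower = 0)
      gsd <- rtnorm(p, h$mean, h$sd, lower = 0)
      g <- c(gmu, gsd)
      eg <- expand_group(hier, g)
      th <- matrix(rtnorm(n * p, rep(eg$mu, each = n),
                          rep(eg$sigma, each = n), lower = 0), n, p)
      lli <- vapply(seq_len(n), function(i)
        loglik_compiled(design, compiled[[i]], th[i, ]), numeric(1))
      if (all(is.finite(lli))) {
        theta[c_, , ] <- th; G[c_, ] <- g
        ll[c_, ] <- lli
        gd[c_, ] <- group_logdens(th, eg$mu, eg$sigma)
        hp[c_] <- log_hyperprior(hier, g)
        break
      }
    }
  }
  if (any(!is.finite(hp)))
    stop("could not initialize all hierarchical chains at finite posterior")

  total_lp <- function() rowSums(ll) + rowSums(gd) + hp

  update_participants <- function() {
    for (i in seq_len(n)) {
      cur <- matrix(theta[, i, ], nc, p)
      jk <- vapply(seq_len(nc), function(ch) sample(seq_len(nc)[-ch], 2L),
                   integer(2))
      prop <- cur + gamma_p * (cur[jk[1, ], , drop = FALSE] -
                                 cur[jk[2, ], , drop = FALSE]) +
        matrix(runif(nc * p, -config$jitter, config$jitter), nc, p)
      ok <- rowSums(prop <= 0) == 0
      llp <- rep(-Inf, nc); gdp <- rep(-Inf, nc)
      for (ch in which(ok)) {
        eg <- expand_group(hier, G[ch, ])
        gdp[ch] <- sum(dtnorm(prop[ch, ], eg$mu, eg$sigma, 0, Inf,
                              log = TRUE))
        if (is.finite(gdp[ch]))
          llp[ch] <- loglik_compiled(design, compiled[[i]], prop[ch, ])
      }
      acc <- log(runif(nc)) < (llp + gdp) - (ll[, i] + gd[, i])
      acc[!is.finite(llp)] <- FALSE
      if (any(acc)) {
        theta[acc, i, ] <<- prop[acc, , drop = FALSE]
        ll[acc, i] <<- llp[acc]
        gd[acc, i] <<- gdp[acc]
      }
    }
  }

  update_group <- function() {
    jk <- vapply(seq_len(nc), function(ch) sample(seq_len(nc)[-ch], 2L),
                 integer(2))
    prop <- G + gamma_g * (G[jk[1, ], , drop = FALSE] -
                             G[jk[2, ], , drop = FALSE]) +
      matrix(runif(nc * gq, -config$jitter, config$jitter), nc, gq)
    for (ch in seq_len(nc)) {
      g <- prop[ch, ]
      if (any(g <= 0)) next
      hpn <- log_hyperprior(hier, g)
      if (!is.finite(hpn)) next
      eg <- expand_group(hier, g)
      gdn <- group_logdens(matrix(theta[ch, , ], n, p), eg$mu, eg$sigma)
      if (log(runif(1)) < (sum(gdn) + hpn) - (sum(gd[ch, ]) + hp[ch])) {
        G[ch, ] <<- g
        gd[ch, ] <<- gdn
        hp[ch] <<- hpn
      }
    }
  }

  migrate_full <- function() {
    lp <- total_lp()
    size <- sample(2:nc, 1L)
    cyc <- sample(seq_len(nc), size)
    pred <- c(cyc[size], cyc[-size])
    old <- list(theta = theta, G = G, ll = ll, gd = gd, hp = hp, lp = lp)
    for (m in seq_len(size)) {
      i <- cyc[m]; pr <- pred[m]
      if (log(runif(1)) < old$lp[pr] - (rowSums(ll) + rowSums(gd) + hp)[i]) {
        theta[i, , ] <<- old$theta[pr, , ]
        G[i, ] <<- old$G[pr, ]
        ll[i, ] <<- old$ll[pr, ]
        gd[i, ] <<- old$gd[pr, ]
        hp[i] <<- old$hp[pr]
      }
    }
  }

  # --- burn-in
  for (chunk in seq_len(config$max_burn_chunks)) {
    hist_g <- array(NA_real_, c(nc, config$burn_chunk, gq))
    for (it in seq_len(config$burn_chunk)) {
      if (runif(1) < config$migration_prob) migrate_full()
      update_participants()
      update_group()
      hist_g[, it, ] <- G
    }
    lp <- total_lp()
    med <- stats::median(lp)
    stuck <- which(lp < med - config$unstuck_gap)
    if (length(stuck) && length(stuck) < nc) {
      donor <- sample(setdiff(seq_len(nc), stuck), length(stuck),
                      replace = TRUE)
      for (m in seq_along(stuck)) {
        i <- stuck[m]; d_ <- donor[m]
        theta[i, , ] <- theta[d_, , ]; G[i, ] <- G[d_, ]
        ll[i, ] <- ll[d_, ]; gd[i, ] <- gd[d_, ]; hp[i] <- hp[d_]
      }
    }
    rh <- vapply(seq_len(gq), function(j) rhat(t(hist_g[, , j])),
                 numeric(1))
    if (!length(stuck) && max(rh) < config$rhat_threshold && chunk >= 2)
      break
  }

  # --- sampling phase
  per_chain <- max(2, ceiling(config$n_retained / nc))
  pars <- hier_par_names(hier, subjects)
  draws <- array(NA_real_, c(nc, per_chain, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  lpmat <- matrix(NA_real_, nc, per_chain)
  for (r in seq_len(per_chain)) {
    for (s_ in seq_len(config$thin)) {
      update_participants()
      update_group()
    }
    for (ch in seq_len(nc))
      draws[ch, r, ] <- c(as.vector(t(matrix(theta[ch, , ], n, p))), G[ch, ])
    lpmat[, r] <- total_lp()
  }
  out <- lba_samples(draws, lpmat, pars, seed = seed %||% NA_integer_,
                     config = config[c("n_retained", "thin",
                                       "migration_prob")])
  out$rhat <- rhat(out)
  out$subjects <- subjects
  out
}
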