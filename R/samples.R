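# Posterior sample container: chains x retained iterations x parameters,
# with the natural-scale log posterior of every retained draw.

#' Construct a posterior-samples object
#'
#' @param draws numeric array (chains x iterations x parameters).
#' @param lp matrix (chains x iterations) of natural-scale log posterior
#'   values for the retained draws.
#' @param pars parameter names (length = dim 3 of draws).
#' @param seed integer seed provenance, or NA.
#' @param config the sampler configuration used, if any.
#' @return object of class \code{"lba_samples"}.
#' @export
lba_samples <- function(draws, lp = NULL, pars = NULL, seed = NA_integer_,
                        config = NULL) {
  stopifnot(length(dim(draws)) == 3)
  pars <- pars %||% dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  stopifnot(length(pars) == dim(draws)[3])
  dimnames(draws) <- list(NULL, NULL, pars)
  if (is.null(lp)) lp <- matrix(0, dim(draws)[1], dim(draws)[2])
  stopifnot(all(dim(lp) == dim(draws)[1:2]))
  structure(list(draws = draws, lp = lp, pars = pars, seed = seed,
                 config = config), class = "lba_samples")
}

#' @export
print.lba_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("LBA posterior samples: %d chains x %d iterations x %d parameters\n",
              d[1], d[2], d[3]))
  cat("parameters:", paste(x$pars, collapse = ", "), "\n")
  if (!is.null(x$rhat))
    cat("max split R-hat:", round(max(x$rhat), 4), "\n")
  invisible(x)
}

#' Pool chains into a draws matrix
#'
#' @param samples an [lba_samples()] object.
#' @return matrix ((chains * iterations) x parameters).
#' @export
pool_draws <- function(samples) {
  d <- dim(samples$draws)
  out <- matrix(aperm(samples$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(out) <- samples$pars
  out
}

# Split each chain's retained iterations in half by iteration order, then
# pool: half 1 fits the proposal moments, half 2 feeds the iterative scheme.
split_halves <- function(samples) {
  d <- dim(samples$draws)
  m <- d[2] %/% 2
  if (m < 1) stop("need at least 2 retained iterations per chain")
  first <- samples$draws[, seq_len(m), , drop = FALSE]
  second <- samples$draws[, (m + 1):d[2], , drop = FALSE]
  flatten <- function(a) {
    out <- matrix(aperm(a, c(2, 1, 3)), dim(a)[1] * dim(a)[2], dim(a)[3])
    colnames(out) <- samples$pars
    out
  }
  list(first = flatten(first), second = flatten(second),
       second_array = second)
}

# Keep only the first n retained iterations per chain such that the pooled
# draw count is approximately `pooled`; used for sample-size grids.
head_samples <- function(samples, pooled) {
  d <- dim(samples$draws)
  keep <- max(2, min(d[2], ceiling(pooled / d[1])))
  lba_samples(samples$draws[, seq_len(keep), , drop = FALSE],
              samples$lp[, seq_len(keep), drop = FALSE],
              samples$pars, samples$seed, samples$config)
}

#' Write posterior samples as CSV plus JSON sidecar
#'
#' The CSV holds flattened draws (chain, iteration, one column per
#' parameter, lp); the sidecar records parameter names, seed and shape so
#' the array round-trips exactly.
#'
#' @param samples an [lba_samples()] object.
#' @param path CSV path; the sidecar is written at \code{paste0(path, ".json")}.
#' @export
write_samples <- function(samples, path) {
  d <- dim(samples$draws)
  flat <- data.frame(chain = rep(seq_len(d[1]), each = d[2]),
                     iteration = rep(seq_len(d[2]), d[1]))
  for (j in seq_len(d[3]))
    flat[[samples$pars[j]]] <- as.vector(t(samples$draws[, , j]))
  flat$lp <- as.vector(t(samples$lp))
  utils::write.csv(flat, path, row.names = FALSE)
  meta <- list(pars = samples$pars, seed = samples$seed,
               n_chains = d[1], n_iterations = d[2],
               config = samples$config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read posterior samples written by [write_samples()]
#'
#' @param path CSV path.
#' @return an [lba_samples()] object.
#' @export
read_samples <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- utils::read.csv(path, check.names = FALSE)
  nc <- meta$n_chains; ni <- meta$n_iterations; pars <- meta$pars
  draws <- array(NA_real_, c(nc, ni, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (j in seq_along(pars))
    draws[, , j] <- matrix(flat[[pars[j]]], nc, ni, byrow = TRUE)
  lp <- matrix(flat$lp, nc, ni, byrow = TRUE)
  lba_samples(draws, lp, pars, seed = meta$seed %||% NA_integer_,
              config = meta$config)
}

#' Write a trial table as CSV
#'
#' Header \code{subject,condition,stimulus,response,rt}, RT in seconds.
#'
#' @param trials a trial data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, require_rows = FALSE)
  utils::write.csv(trials[, c("subject", "condition", "stimulus",
                              "response", "rt")], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV path with the [write_trials()] header.
#' @return a trial data frame.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path)
  validate_trials(tr, require_rows = FALSE)
  for (col in c("subject", "condition", "stimulus", "response"))
    tr[[col]] <- as.character(tr[[col]])
  if (!is.numeric(tr$rt)) stop("rt column must be numeric")
  tr
}
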