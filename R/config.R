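# Declarative model configuration files (YAML or JSON).
#
# A config names the model family and optionally overrides priors or the
# restricted-model constants, e.g.
#   type: single            # or hier
#   model: restricted       # full/restricted or V/0/B/B_res
#   v_true_fixed: 3.55
#   prior:                  # optional rows overriding the defaults
#     - {par: A, mean: 1, sd: 1, lower: 0, upper: .inf}

#' Read a model configuration file
#'
#' @param path YAML or JSON file (dispatch on extension).
#' @return an [lba_design()] or [hier_design()] according to the config.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  type <- cfg$type %||% "single"
  if (type == "hier") return(hier_design(as.character(cfg$model)))
  design <- single_design(cfg$model %||% "full",
                          v_true_fixed = cfg$v_true_fixed %||% 3.55)
  if (!is.null(cfg$prior)) {
    # JSON readers simplify the row list to a data frame; YAML yields a
    # list of row lists
    ov <- if (is.data.frame(cfg$prior)) cfg$prior
    else as.data.frame(do.call(rbind, lapply(cfg$prior, as.data.frame)))
    ov$par <- as.character(ov$par)
    for (i in seq_len(nrow(ov))) {
      j <- match(ov$par[i], design$prior$par)
      if (is.na(j)) stop("prior override for unknown parameter: ", ov$par[i])
      for (col in c("mean", "sd", "lower", "upper"))
        if (!is.null(ov[[col]][i]) && !is.na(ov[[col]][i]))
          design$prior[[col]][j] <- as.numeric(ov[[col]][i])
    }
    if (any(design$prior$sd <= 0) ||
        any(design$prior$lower >= design$prior$upper))
      stop("invalid prior override: need sd > 0 and lower < upper")
  }
  design
}

#' Write a model configuration file
#'
#' @param design an [lba_design()] or [hier_design()].
#' @param path output path (.yaml/.yml or .json).
#' @export
write_model_config <- function(design, path) {
  if (inherits(design, "lba_hier")) {
    cfg <- list(type = "hier", model = design$name)
  } else {
    cfg <- list(type = "single", model = design$name)
    if ("v_true" %in% names(design$constants))
      cfg$v_true_fixed <- unname(design$constants[["v_true"]])
    cfg$prior <- lapply(seq_len(nrow(design$prior)), function(i)
      as.list(design$prior[i, ]))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}
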