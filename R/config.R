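#' Read a run configuration file
#'
#' Configurations are structured text, JSON or YAML (decided by extension,
#' with a JSON-then-YAML fallback for other extensions). A configuration
#' holds three blocks: `model` (branch probabilities, costs, residual
#' calibration constants, per-class activity counts per arm, sequelae class,
#' horizon), `utilities` (per-class mean and sd) and `psa` (iterations, WTP
#' grid).
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
             error = function(e) yaml::read_yaml(path))
  }
  for (block in c("model", "utilities"))
    if (is.null(cfg[[block]])) stop("config is missing the '", block, "' block")
  cfg
}

#' Path to the shipped baseline configuration
#'
#' The baseline config encodes the published model: branch probabilities,
#' Table-2 arm costs, complication costs, pooled Table-1 activity counts,
#' the calibrated utility key and the residual cost constants (see the
#' methods vignette for the calibration).
#'
#' @return File path inside the installed package.
#' @export
baseline_config_path <- function() {
  system.file("extdata", "baseline_config.json", package = "aclcea",
              mustWork = TRUE)
}

#' Load the shipped baseline configuration
#'
#' @return Named list (see [read_run_config()]).
#' @export
baseline_config <- function() read_run_config(baseline_config_path())

#' Build model parameters from a configuration
#'
#' @param cfg List from [read_run_config()].
#' @param overrides Named list of scalar `model` fields to replace
#'   (type-checked: unknown names are an error).
#' @return A [model_params()].
#' @export
config_model_params <- function(cfg, overrides = list()) {
  m <- cfg$model
  if (length(overrides)) {
    known <- c("p_fail", "p_crossover", "p_seq_operative", "p_seq_conservative",
               "split_oa_operative", "split_oa_conservative",
               "cost_surgical", "cost_conservative", "cost_oa", "cost_meniscus",
               "residual_cost_operative", "residual_cost_conservative",
               "sequelae_class", "horizon_months")
    unknown <- setdiff(names(overrides), known)
    if (length(unknown))
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (nm == "sequelae_class") {
        if (!v %in% activity_classes()) stop("invalid sequelae_class: ", v)
      } else {
        v <- suppressWarnings(as.numeric(v))
        if (is.na(v)) stop("parameter '", nm, "' must be numeric")
      }
      m[[nm]] <- v
    }
  }
  to_dist <- function(x)
    activity_distribution(unlist(x)[activity_classes()], normalize = TRUE)
  model_params(
    p_fail = m$p_fail, p_crossover = m$p_crossover,
    p_seq_operative = m$p_seq_operative,
    p_seq_conservative = m$p_seq_conservative,
    split_oa_operative = m$split_oa_operative,
    split_oa_conservative = m$split_oa_conservative,
    cost_surgical = m$cost_surgical, cost_conservative = m$cost_conservative,
    cost_oa = m$cost_oa, cost_meniscus = m$cost_meniscus,
    residual_cost_operative = m$residual_cost_operative,
    residual_cost_conservative = m$residual_cost_conservative,
    dist_operative = to_dist(m$counts_operative),
    dist_conservative = to_dist(m$counts_conservative),
    sequelae_class = m$sequelae_class,
    horizon_months = m$horizon_months
  )
}

#' Build a utility key from a configuration
#'
#' @param cfg List from [read_run_config()].
#' @return A [utility_key()].
#' @export
config_utility_key <- function(cfg) {
  u <- cfg$utilities
  cls <- intersect(c("0", activity_classes()), names(u))
  utility_key(
    mean = vapply(stats::setNames(cls, cls), function(cl) u[[cl]]$mean, numeric(1)),
    sd = vapply(stats::setNames(cls, cls), function(cl) {
      s <- u[[cl]]$sd
      if (is.null(s)) 0 else s
    }, numeric(1))
  )
}

#' Build a PSA spec from a configuration
#'
#' @param cfg List from [read_run_config()].
#' @param seed,n_iterations Optional overrides of the config values.
#' @return A [psa_spec()].
#' @export
config_psa_spec <- function(cfg, seed = NULL, n_iterations = NULL) {
  p <- cfg$psa
  if (is.null(p)) p <- list()
  n <- if (!is.null(n_iterations)) n_iterations
       else if (!is.null(p$n_iterations)) p$n_iterations else 10000L
  s <- if (!is.null(seed)) seed
       else if (!is.null(p$seed)) p$seed else 1L
  psa_spec(config_utility_key(cfg), n_iterations = n, seed = s)
}

#' WTP grid from a configuration
#'
#' @param cfg List from [read_run_config()].
#' @return Numeric WTP grid (default 0 to 100,000 by 1,000 USD/QALY).
#' @export
config_wtp_grid <- function(cfg) {
  p <- cfg$psa
  if (is.null(p)) p <- list()
  wtp_max <- if (!is.null(p$wtp_max)) p$wtp_max else 100000
  wtp_step <- if (!is.null(p$wtp_step)) p$wtp_step else 1000
  seq(0, wtp_max, by = wtp_step)
}

#' Stable hash of a configuration (provenance)
#'
#' Polynomial rolling hash over the canonical JSON serialization; enough to
#' tell two configurations apart in run metadata, not a cryptographic
#' digest.
#'
#' @param cfg List.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  txt <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
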