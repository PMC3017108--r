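# YAML run configuration: a structured-text override tree over the reference
# parameter set plus an experiment descriptor.  Sweeps and mutants are plain
# config diffs.

config_param_keys <- function() {
  c("E", "nu", "eps_c", "K", "eta_c", "eta_bm", "eta_vo",
    "F_A_paneth", "F_A_other", "R0", "tau", "n_growth_steps",
    "V_p_ratio", "vp_reference", "lambda_max", "omega",
    "eps_knot_paneth", "eps_knot_other", "z_p", "z_d",
    "lp_paneth", "lp_goblet", "tp_notch", "td_notch", "t_paneth",
    "brdu_label_fraction", "t_section", "dt_max", "wnt_mode", "notch_mode")
}

config_shape_keys <- function() c("z0", "r0", "lambda1", "lambda2")

config_experiment_keys <- function() {
  c("kind", "duration", "warmup", "obs_dt", "seed", "replicates",
    "out_dir", "ablate_lineages", "perturbation", "sweep_param",
    "sweep_values", "sample_times", "n_halfcrypts")
}

#' Load a run configuration
#'
#' Reads a YAML configuration. Unspecified fields default to the reference
#' parameter set; unknown keys are rejected with their location. An empty
#' file yields the pure reference configuration. Configurations round-trip
#' losslessly through [save_config()].
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: list with `params`
#'   (a [model_params()]), `experiment` (descriptor list) and `raw`
#'   (the override tree).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

build_config <- function(raw) {
  known_top <- c("schema", "shape", "params", "experiment")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    stop("unknown configuration key(s) at top level: ",
         paste(bad, collapse = ", "))
  if (!is.null(raw$schema) && raw$schema != 1L)
    stop("unsupported configuration schema version: ", raw$schema)
  shp <- raw$shape
  bad <- setdiff(names(shp), config_shape_keys())
  if (length(bad))
    stop("unknown configuration key(s) under 'shape': ",
         paste(bad, collapse = ", "))
  prm <- raw$params
  bad <- setdiff(names(prm), config_param_keys())
  if (length(bad))
    stop("unknown configuration key(s) under 'params': ",
         paste(bad, collapse = ", "))
  exp_ <- raw$experiment
  bad <- setdiff(names(exp_), config_experiment_keys())
  if (length(bad))
    stop("unknown configuration key(s) under 'experiment': ",
         paste(bad, collapse = ", "))

  shape <- do.call(crypt_shape, if (is.null(shp)) list() else shp)
  args <- if (is.null(prm)) list() else prm
  args$shape <- shape
  params <- do.call(model_params, args)

  experiment <- utils::modifyList(
    list(kind = "steady_state", duration = 240, warmup = 240, obs_dt = 12,
         seed = 1L, replicates = 1L, out_dir = ".",
         sample_times = c(2, 24), n_halfcrypts = 50),
    if (is.null(exp_)) list() else exp_)
  structure(list(params = params, experiment = experiment,
                 raw = raw), class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- config$raw
  if (is.null(raw$schema)) raw$schema <- 1L
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration (experiment:", x$experiment$kind, ")\n")
  print(x$params)
  invisible(x)
}
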