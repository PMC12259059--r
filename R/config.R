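# Run configuration: a structured YAML file with force-field, system,
# integrator and analysis blocks.  Unknown keys are rejected so typos fail
# loudly, and serialization round-trips numeric values losslessly.

.config_schema <- list(
  forcefield = c("lambda_pp", "lambda_pd", "lambda_dd", "epsilon",
                 "k_bond", "r0", "k_angle", "theta0_deg", "cutoff_factor",
                 "exclude_bonded", "species"),
  system = c("n_protein", "dna_length", "n_dna_chains", "box_edge",
             "placement"),
  integrator = c("temperature", "t_damp_ps", "dt_fs", "n_steps", "cadence",
                 "nve"),
  analysis = c("cluster_cutoff", "shell_width", "n_blocks",
               "discard_fraction", "bound_threshold", "n_interfaces",
               "lags_ns", "n_max_modes", "residual_threshold",
               "concentration_factor"),
  output = c("trajectory", "xyz", "log", "report"),
  seed = NULL)

#' Default run configuration
#'
#' Full parameter set of the condensate model with the standard values; use
#' it as a template and override fields before [write_run_config()].
#'
#' @return nested named list (a run config).
#' @export
default_run_config <- function() {
  list(
    forcefield = list(lambda_pp = 1, lambda_pd = 1, lambda_dd = -1,
                     epsilon = 0.2, k_bond = 20, r0 = 5.5, k_angle = 20,
                     theta0_deg = 180, cutoff_factor = 3,
                     exclude_bonded = TRUE),
    system = list(n_protein = 5000L, dna_length = 250L, n_dna_chains = 20L,
                  box_edge = 2000, placement = "central-random"),
    integrator = list(temperature = 300, t_damp_ps = 1000, dt_fs = 10,
                      n_steps = 10000L, cadence = 1000L, nve = FALSE),
    analysis = list(shell_width = 10, n_blocks = 5L,
                    discard_fraction = 0.2, bound_threshold = 55,
                    n_interfaces = 1L, n_max_modes = 6L,
                    residual_threshold = 0.1, concentration_factor = 1),
    output = list(trajectory = "trajectory.rds", xyz = NULL,
                  log = "run_log.csv", report = "report.json"),
    seed = 1L)
}

#' Read / write a run configuration
#'
#' YAML round trip with validation: blocks and keys outside the schema are
#' rejected; numbers survive with 17 significant digits.
#'
#' @param path YAML file path.
#' @param config a run-config list (see [default_run_config()]).
#' @return `read_run_config` returns the validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  writeLines(yaml::as.yaml(config, precision = 17L), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  bad <- setdiff(names(config), names(.config_schema))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Instantiate model/spec/params objects from a run config
#' @param config a run-config list.
#' @return list with `model`, `spec`, `params`, `analysis`, `output`,
#'   `n_steps`, `cadence`, `nve`.
#' @export
config_objects <- function(config) {
  validate_run_config(config)
  ff <- modifyList(default_run_config()$forcefield,
                   config$forcefield %||% list())
  sys <- modifyList(default_run_config()$system, config$system %||% list())
  itg <- modifyList(default_run_config()$integrator,
                    config$integrator %||% list())
  an <- modifyList(default_run_config()$analysis,
                   config$analysis %||% list())
  seed <- config$seed %||% 1L
  model <- interaction_model(lambda_pp = ff$lambda_pp,
                             lambda_pd = ff$lambda_pd,
                             lambda_dd = ff$lambda_dd,
                             epsilon = ff$epsilon, k_bond = ff$k_bond,
                             r0 = ff$r0, k_angle = ff$k_angle,
                             theta0 = ff$theta0_deg * pi / 180,
                             cutoff_factor = ff$cutoff_factor,
                             exclude_bonded = ff$exclude_bonded)
  spec <- system_spec(n_protein = sys$n_protein,
                      dna_length = sys$dna_length,
                      n_dna_chains = sys$n_dna_chains,
                      box_edge = sys$box_edge, seed = seed,
                      placement = sys$placement)
  params <- thermostat_params(temperature = itg$temperature,
                              t_damp_ps = itg$t_damp_ps,
                              dt_fs = itg$dt_fs, seed = seed)
  list(model = model, spec = spec, params = params, analysis = an,
       output = config$output %||% default_run_config()$output,
       n_steps = itg$n_steps, cadence = itg$cadence,
       nve = isTRUE(itg$nve), seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
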