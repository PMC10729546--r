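# Configuration and plain-text serialization. Configs are flat YAML files
# keyed by the model's parameter symbols plus a small set of run settings;
# every output is a delimited text table so downstream plotting stays
# optional and decoupled.

.config_keys <- c("initial", "step", "horizon", "conv_tol", "cycle_amp",
                  "tol", "seed", "n_runs")

#' Load (or default) a run configuration
#'
#' A configuration is a flat YAML mapping. Recognized keys are the 17
#' parameter symbols (Mg1 ... Be) and the run settings `initial` (length-3
#' probability triple), `step` (0.01), `horizon` (100), `conv_tol` (1e-3),
#' `cycle_amp` (0.05), `tol` (1e-9, eigenvalue zero threshold), `seed`
#' (42) and `n_runs` (50); defaults in parentheses, parameters defaulting
#' to the Anhui baseline. Unknown keys are rejected by name. `path = NULL`
#' yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return A list of class `"care_config"` with elements `params`
#'   (`"care_params"`) and the run settings above.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$params[["Nc"]]
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), c(.param_names, .config_keys))
    if (length(unknown) > 0L)
      stop("unknown key ", paste(unknown, collapse = ", "))
  }
  p <- unclass(anhui_baseline())
  for (nm in intersect(names(vals), .param_names)) p[[nm]] <- vals[[nm]]
  cfg <- list(
    params = validate_parameters(p),
    initial = as_state(if (is.null(vals$initial)) c(0.5, 0.5, 0.5)
                       else vals$initial),
    step = if (is.null(vals$step)) 0.01 else vals$step,
    horizon = if (is.null(vals$horizon)) 100 else vals$horizon,
    conv_tol = if (is.null(vals$conv_tol)) 1e-3 else vals$conv_tol,
    cycle_amp = if (is.null(vals$cycle_amp)) 0.05 else vals$cycle_amp,
    tol = if (is.null(vals$tol)) 1e-9 else vals$tol,
    seed = if (is.null(vals$seed)) 42L else as.integer(vals$seed),
    n_runs = if (is.null(vals$n_runs)) 50L else as.integer(vals$n_runs))
  if (cfg$step <= 0) stop("step must be positive")
  if (cfg$horizon < cfg$step) stop("horizon must be at least one step")
  class(cfg) <- "care_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a `"care_config"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "care_config"))
  out <- c(as.list(unclass(config$params)),
           list(initial = as.numeric(config$initial),
                step = config$step, horizon = config$horizon,
                conv_tol = config$conv_tol, cycle_amp = config$cycle_amp,
                tol = config$tol, seed = config$seed,
                n_runs = config$n_runs))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

# Full-precision delimited writer shared by the table exporters.
#' @keywords internal
.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as a tab-delimited table
#'
#' Columns t, x, y, z, one row per sample, full precision.
#'
#' @param traj a `"care_trajectory"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "care_trajectory"))
  df <- data.frame(t = traj$times, x = traj$states[, "x"],
                   y = traj$states[, "y"], z = traj$states[, "z"])
  .write_table(df, path)
}

#' Export an equilibrium report as a tab-delimited table
#'
#' One row per cube vertex: vertex, the three closed-form eigenvalues and
#' the Lyapunov classification.
#'
#' @param equilibria output of [enumerate_equilibria()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_equilibria <- function(equilibria, path) {
  .write_table(as.data.frame(equilibria), path)
}

#' Export a sweep table
#'
#' @param sweep output of [sweep_parameter()] or [outcome_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  df <- as.data.frame(sweep)
  attr(df, "trajectories") <- NULL
  .write_table(df, path)
}
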