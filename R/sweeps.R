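# One-at-a-time parameter sensitivity sweeps.

# Which agent's coordinate a swept parameter primarily drives.
#' @keywords internal
.focal_agent <- c(
  Mg1 = "x", Mg2 = "x", Sg1 = "x", Sg2 = "x",
  Mc1 = "y", Mc2 = "y", Nc = "y", Bc = "y", Sc = "y", c = "y",
  Lc1 = "y", Lc2 = "y",
  Me = "z", He1 = "z", He2 = "z", Ne = "z", Be = "z")

#' Default sensitivity grids
#'
#' The one-at-a-time grids used in the sensitivity analyses: each mirrors
#' the values examined around the Anhui baseline for that parameter.
#'
#' @return Named list of numeric vectors.
#' @export
default_sweep_grids <- function() {
  list(
    Mg1 = c(110, 130, 150, 170, 190),
    Sg1 = c(150, 200, 250, 300, 350),
    Nc  = c(10, 30, 50, 70, 80, 90),
    c   = c(100, 150, 200, 250, 300),
    Lc1 = c(0, 50, 150, 250),
    Lc2 = c(0, 50, 150, 250),
    Me  = c(115, 140, 165, 190, 215),
    Be  = c(0, 30, 100, 200),
    Ne  = c(10, 30, 50, 70, 90))
}

#' Sweep a single parameter
#'
#' Replaces one parameter field with each value in turn (all other fields
#' at `params`), integrates from `initial`, classifies the outcome, and
#' records the focal agent's limiting probability and convergence times.
#' Values that break a validation invariant (negativity or one of the
#' strict orderings) yield a flagged row rather than an error.
#'
#' @param params baseline `"care_params"` vector.
#' @param name parameter to sweep (one of the 17 field names).
#' @param values numeric vector of replacement values.
#' @param initial initial state for every run (default (0.5, 0.5, 0.5)).
#' @param horizon,step integrator settings; the default horizon of 200 is
#'   long enough for cycle detection.
#' @param conv_tol,cycle_amp outcome-detection tolerances.
#' @return A data frame of class `"care_sweep"`, one row per value:
#'   `parameter`, `value`, `outcome` (or `"invalid: <reason>"`), `x_lim`,
#'   `y_lim`, `z_lim`, `focal` (focal coordinate name), `focal_lim`,
#'   `t_converge` (sup-norm time to convergence), `t_converge_focal`
#'   (focal coordinate's own settling time). Trajectories are attached as
#'   attribute `"trajectories"`.
#' @export
#' @examples
#' sweep_parameter(anhui_baseline(), "Nc", c(10, 70), horizon = 100)
sweep_parameter <- function(params, name, values,
                            initial = c(0.5, 0.5, 0.5),
                            horizon = 200, step = 0.01,
                            conv_tol = 1e-3, cycle_amp = 0.05) {
  p <- validate_parameters(params)
  if (!name %in% .param_names)
    stop("unknown parameter: ", name)
  if (length(values) < 1L) stop("values must be non-empty")
  s0 <- as_state(initial)
  focal <- .focal_agent[[name]]

  sets <- vector("list", length(values))
  invalid <- character(length(values))
  for (i in seq_along(values)) {
    repl <- stats::setNames(list(p), "params")
    repl[[name]] <- values[i]
    sets[[i]] <- tryCatch(do.call(set_params, repl),
                          error = function(e) {
                            invalid[i] <<- conditionMessage(e)
                            NULL
                          })
  }
  ok <- !vapply(sets, is.null, logical(1L))
  trajs <- vector("list", length(values))
  if (any(ok)) {
    pm <- .param_matrix(sets[ok])
    init <- matrix(s0, sum(ok), 3L, byrow = TRUE)
    sim <- .rk4_paths(pm, init, step, horizon)
    kk <- which(ok)
    for (j in seq_along(kk))
      trajs[[kk[j]]] <- .make_trajectory(sim, j, sets[[kk[j]]], step,
                                         horizon, conv_tol, cycle_amp)
  }
  rows <- lapply(seq_along(values), function(i) {
    if (!ok[i])
      return(data.frame(parameter = name, value = values[i],
                        outcome = paste0("invalid: ", invalid[i]),
                        x_lim = NA_real_, y_lim = NA_real_, z_lim = NA_real_,
                        focal = focal, focal_lim = NA_real_,
                        t_converge = NA_real_, t_converge_focal = NA_real_,
                        stringsAsFactors = FALSE))
    tr <- trajs[[i]]
    fin <- tr$states[nrow(tr$states), ]
    data.frame(parameter = name, value = values[i], outcome = tr$outcome,
               x_lim = fin[["x"]], y_lim = fin[["y"]], z_lim = fin[["z"]],
               focal = focal, focal_lim = fin[[focal]],
               t_converge = tr$t_converge,
               t_converge_focal = .coord_converge_time(tr, focal, conv_tol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  class(out) <- c("care_sweep", class(out))
  out
}

#' Combine sweep results into one ordered grid
#'
#' @param sweeps a single `"care_sweep"` data frame or a list of them.
#' @return One data frame with the same columns, ordered by parameter name
#'   then value, row names dropped.
#' @export
#' @examples
#' g <- outcome_grid(list(
#'   sweep_parameter(anhui_baseline(), "Nc", c(10, 70), horizon = 100),
#'   sweep_parameter(anhui_baseline(), "Be", 200, horizon = 100)))
outcome_grid <- function(sweeps) {
  if (is.data.frame(sweeps)) sweeps <- list(sweeps)
  if (length(sweeps) == 0L) stop("no sweep results supplied")
  tabs <- lapply(sweeps, function(s) {
    attr(s, "trajectories") <- NULL
    as.data.frame(s)
  })
  out <- do.call(rbind, tabs)
  out <- out[order(out$parameter, out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run every default sensitivity grid
#'
#' Convenience wrapper: sweeps all parameters in [default_sweep_grids()]
#' one at a time from the baseline and returns the combined
#' [outcome_grid()].
#'
#' @inheritParams sweep_parameter
#' @return Combined sweep data frame.
#' @export
run_all_sweeps <- function(params = anhui_baseline(),
                           initial = c(0.5, 0.5, 0.5),
                           horizon = 200, step = 0.01) {
  grids <- default_sweep_grids()
  outcome_grid(lapply(names(grids), function(nm)
    sweep_parameter(params, nm, grids[[nm]], initial = initial,
                    horizon = horizon, step = step)))
}
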