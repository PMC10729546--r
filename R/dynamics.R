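# Numerical integration of the replicator system on the unit cube,
# convergence/cycle detection, and the initial-willingness experiments.

#' @keywords internal
.clip01 <- function(v) pmin(1, pmax(0, v))

# Vectorized projected RK4 core. `pm` is an n x 17 parameter matrix (one
# row per path, or a single row recycled), `init` an n x 3 matrix of
# initial states. Classic fixed-step RK4; both the stage states and the
# end-of-step state are projected onto [0,1]^3. Stage projection matters:
# the quadratic factors p(1-p) change sign outside the cube, and for large
# payoff magnitudes an unprojected stage can fabricate spurious fixed
# points of the discrete map.
#' @keywords internal
.rk4_paths <- function(pm, init, step, horizon, track_overshoot = FALSE) {
  nt <- as.integer(round(horizon / step))
  if (nt < 1L) stop("horizon must be at least one step")
  n <- nrow(init)
  g <- function(nm) if (nrow(pm) == 1L) pm[1L, nm] else pm[, nm]
  ax0 <- g("Sg1") + g("Lc1") - g("Mg1") + g("Mg2") + g("Sg2")
  axy <- -(g("Lc1") + g("Sg2") + g("Nc")); axz <- -g("Ne")
  by0 <- g("Mc2") - g("Mc1") - g("c")
  byx <- g("Nc") + g("Lc1"); byz <- g("Sc") + g("Lc2")
  bz0 <- g("Lc2") + g("Be") - g("Me") + g("He2")
  bzx <- g("Ne"); bzy <- g("He1") - g("He2") - g("Lc2")
  f <- function(x, y, z) list(
    x = x * (1 - x) * (ax0 + axy * y + axz * z),
    y = y * (1 - y) * (by0 + byx * x + byz * z),
    z = z * (1 - z) * (bz0 + bzx * x + bzy * y))
  X <- matrix(0, nt + 1L, n); Y <- X; Z <- X
  x <- init[, 1L]; y <- init[, 2L]; z <- init[, 3L]
  X[1L, ] <- x; Y[1L, ] <- y; Z[1L, ] <- z
  h <- step
  overshoot <- 0
  for (i in seq_len(nt)) {
    k1 <- f(x, y, z)
    k2 <- f(.clip01(x + h / 2 * k1$x), .clip01(y + h / 2 * k1$y),
            .clip01(z + h / 2 * k1$z))
    k3 <- f(.clip01(x + h / 2 * k2$x), .clip01(y + h / 2 * k2$y),
            .clip01(z + h / 2 * k2$z))
    k4 <- f(.clip01(x + h * k3$x), .clip01(y + h * k3$y),
            .clip01(z + h * k3$z))
    xn <- x + h / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x)
    yn <- y + h / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
    zn <- z + h / 6 * (k1$z + 2 * k2$z + 2 * k3$z + k4$z)
    if (track_overshoot) {
      pre <- c(xn, yn, zn)
      overshoot <- max(overshoot, max(pre) - 1, -min(pre))
    }
    x <- .clip01(xn); y <- .clip01(yn); z <- .clip01(zn)
    X[i + 1L, ] <- x; Y[i + 1L, ] <- y; Z[i + 1L, ] <- z
  }
  out <- list(times = seq(0, by = h, length.out = nt + 1L),
              x = X, y = Y, z = Z)
  if (track_overshoot) out$overshoot <- overshoot
  out
}

#' @keywords internal
.param_matrix <- function(params_list) {
  if (inherits(params_list, "care_params")) params_list <- list(params_list)
  do.call(rbind, lapply(params_list, function(p)
    unclass(validate_parameters(p))))
}

# Wrap one column of a .rk4_paths result into a care_trajectory.
#' @keywords internal
.make_trajectory <- function(sim, j, params, step, horizon,
                             conv_tol = 1e-3, cycle_amp = 0.05) {
  states <- cbind(x = sim$x[, j], y = sim$y[, j], z = sim$z[, j])
  traj <- structure(
    list(times = sim$times, states = states, params = params,
         step = step, horizon = horizon),
    class = "care_trajectory")
  o <- detect_outcome(traj, conv_tol = conv_tol, cycle_amp = cycle_amp)
  traj$outcome <- o$outcome
  traj$vertex <- o$vertex
  traj$t_converge <- o$t_converge
  traj
}

#' Integrate one replicator trajectory
#'
#' Classic fixed-step fourth-order Runge--Kutta applied to
#' [replicator_rhs()], with all stage and step states projected onto the
#' unit cube. Deterministic for fixed inputs. The returned trajectory is
#' already classified by [detect_outcome()] with the default tolerances.
#'
#' @param params a `"care_params"` vector.
#' @param initial initial probability triple (boundary values allowed).
#' @param horizon integration length in dimensionless time (default 100;
#'   use 200 when probing possible cyclic regimes).
#' @param step RK4 step size (default 0.01).
#' @param conv_tol,cycle_amp outcome-detection tolerances, see
#'   [detect_outcome()].
#' @return A `"care_trajectory"`: list with `times`, `states` (matrix with
#'   columns x, y, z), `params`, `step`, `horizon`, `outcome`, `vertex`,
#'   `t_converge`.
#' @export
#' @examples
#' tr <- integrate_trajectory(anhui_baseline(), c(0.5, 0.5, 0.5))
#' tr$outcome
#' tr$vertex
integrate_trajectory <- function(params, initial = c(0.5, 0.5, 0.5),
                                 horizon = 100, step = 0.01,
                                 conv_tol = 1e-3, cycle_amp = 0.05) {
  p <- validate_parameters(params)
  s0 <- as_state(initial)
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  if (!is.numeric(horizon) || horizon < step)
    stop("horizon must be at least one step")
  sim <- .rk4_paths(.param_matrix(p), matrix(s0, 1L, 3L), step, horizon)
  .make_trajectory(sim, 1L, p, step, horizon, conv_tol, cycle_amp)
}

#' Classify the outcome of a trajectory
#'
#' A trajectory has `converged` to vertex v when its sup-norm distance to v
#' stays below `conv_tol` throughout the final 10% of samples (v is the
#' componentwise rounding of the final state). Otherwise it is `cyclic`
#' when at least one coordinate still ranges over more than `cycle_amp`
#' during the final 50% of samples (sustained oscillation), and
#' `not_converged` otherwise (e.g. slow drift toward a degenerate edge of
#' equilibria).
#'
#' @param traj a `"care_trajectory"` (the `outcome` field, if present, is
#'   ignored and recomputed).
#' @param conv_tol sup-norm convergence tolerance (default 1e-3).
#' @param cycle_amp minimal sustained amplitude that counts as cycling
#'   (default 0.05).
#' @return A list with `outcome` (`"converged"`, `"cyclic"`,
#'   `"not_converged"`), `vertex` (numeric triple or `NULL`) and
#'   `t_converge` (time from which the trajectory stays within `conv_tol`
#'   of the vertex; `NA` unless converged).
#' @export
detect_outcome <- function(traj, conv_tol = 1e-3, cycle_amp = 0.05) {
  st <- traj$states
  n <- nrow(st)
  if (is.null(n) || n < 10L) stop("trajectory needs at least 10 samples")
  final <- st[n, ]
  v <- round(final)
  tail_idx <- seq.int(ceiling(0.9 * n), n)
  dist_tail <- apply(abs(st[tail_idx, , drop = FALSE] -
                           matrix(v, length(tail_idx), 3L, byrow = TRUE)),
                     1L, max)
  if (max(dist_tail) < conv_tol) {
    d_all <- apply(abs(st - matrix(v, n, 3L, byrow = TRUE)), 1L, max)
    out_of_tol <- which(d_all >= conv_tol)
    t_conv <- if (length(out_of_tol) == 0L) traj$times[1L]
              else traj$times[max(out_of_tol) + 1L]
    return(list(outcome = "converged", vertex = unname(v),
                t_converge = t_conv))
  }
  half_idx <- seq.int(ceiling(0.5 * n), n)
  rng <- apply(st[half_idx, , drop = FALSE], 2L,
               function(u) diff(range(u)))
  if (any(rng > cycle_amp))
    return(list(outcome = "cyclic", vertex = NULL, t_converge = NA_real_))
  list(outcome = "not_converged", vertex = NULL, t_converge = NA_real_)
}

# Time from which a single coordinate stays within conv_tol of its own
# rounded limit; NA when the coordinate does not settle at 0 or 1.
#' @keywords internal
.coord_converge_time <- function(traj, coord, conv_tol = 1e-3) {
  u <- traj$states[, coord]
  n <- length(u)
  lim <- round(u[n])
  d <- abs(u - lim)
  if (max(d[seq.int(ceiling(0.9 * n), n)]) >= conv_tol) return(NA_real_)
  bad <- which(d >= conv_tol)
  if (length(bad) == 0L) traj$times[1L] else traj$times[max(bad) + 1L]
}

#' Initial-willingness sweep
#'
#' Holds one agent's initial probability fixed and varies the other two
#' over a grid, integrating each combination. This reproduces the
#' initial-value experiments in which, e.g., the government starts at
#' x = 0.5 while y and z range over 0.1 to 0.9.
#'
#' @param params a `"care_params"` vector.
#' @param fixed_agent which coordinate is held fixed: `"x"`, `"y"` or
#'   `"z"`.
#' @param fixed_value the fixed initial probability (default 0.5).
#' @param grid values taken by each of the two free coordinates; must lie
#'   strictly inside (0, 1) (vertex-degenerate starts are rejected).
#' @param horizon,step integrator settings.
#' @return A list with `summary` (data frame: the two free initial values,
#'   x0, y0, z0, outcome, x_lim, y_lim, z_lim, t_converge) and
#'   `trajectories` (list of `"care_trajectory"` objects, one per grid
#'   combination).
#' @export
#' @examples
#' sw <- initial_value_sweep(anhui_baseline(), "x", 0.5,
#'                           grid = c(0.1, 0.5, 0.9), horizon = 50)
#' sw$summary
initial_value_sweep <- function(params, fixed_agent = c("x", "y", "z"),
                                fixed_value = 0.5,
                                grid = seq(0.1, 0.9, by = 0.1),
                                horizon = 100, step = 0.01) {
  p <- validate_parameters(params)
  fixed_agent <- match.arg(fixed_agent)
  if (any(grid <= 0) || any(grid >= 1))
    stop("grid values must lie strictly inside (0, 1)")
  if (fixed_value < 0 || fixed_value > 1)
    stop("fixed_value must lie in [0, 1]")
  free <- setdiff(c("x", "y", "z"), fixed_agent)
  combos <- expand.grid(a = grid, b = grid, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- free
  init <- matrix(fixed_value, nrow(combos), 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  init[, free[1L]] <- combos[[free[1L]]]
  init[, free[2L]] <- combos[[free[2L]]]
  sim <- .rk4_paths(.param_matrix(p), init, step, horizon)
  trajs <- lapply(seq_len(nrow(init)), function(j)
    .make_trajectory(sim, j, p, step, horizon))
  summ <- do.call(rbind, lapply(seq_along(trajs), function(j) {
    tr <- trajs[[j]]
    fin <- tr$states[nrow(tr$states), ]
    data.frame(combos[j, , drop = FALSE],
               x0 = init[j, 1L], y0 = init[j, 2L], z0 = init[j, 3L],
               outcome = tr$outcome,
               x_lim = fin[["x"]], y_lim = fin[["y"]], z_lim = fin[["z"]],
               t_converge = tr$t_converge,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(summary = summ, trajectories = trajs)
}

#' Repeated-evolution experiment from randomized starts
#'
#' Draws `n_runs` initial states uniformly from (0.05, 0.95)^3 with a fixed
#' seed, integrates each, and tallies the outcomes. When every converged
#' run reaches the same vertex, that vertex is reported as the consensus.
#'
#' @param params a `"care_params"` vector.
#' @param n_runs number of independent trajectories (default 50).
#' @param seed RNG seed for the initial-state draws (the only randomness).
#' @param horizon,step integrator settings.
#' @return A list with `runs` (data frame: x0, y0, z0, outcome, x_lim,
#'   y_lim, z_lim, t_converge), `tally` (outcome counts), `consensus`
#'   (vertex triple or `NULL`) and `seed`.
#' @export
#' @examples
#' ex <- replicate_convergence_experiment(anhui_baseline(), n_runs = 10,
#'                                        seed = 1)
#' ex$consensus
replicate_convergence_experiment <- function(params, n_runs = 50, seed = 42,
                                             horizon = 100, step = 0.01) {
  p <- validate_parameters(params)
  if (n_runs < 1L) stop("n_runs must be at least 1")
  init <- sample_initial_states(n_runs, seed = seed)
  sim <- .rk4_paths(.param_matrix(p), init, step, horizon)
  trajs <- lapply(seq_len(n_runs), function(j)
    .make_trajectory(sim, j, p, step, horizon))
  runs <- do.call(rbind, lapply(seq_len(n_runs), function(j) {
    tr <- trajs[[j]]
    fin <- tr$states[nrow(tr$states), ]
    data.frame(x0 = init[j, 1L], y0 = init[j, 2L], z0 = init[j, 3L],
               outcome = tr$outcome,
               x_lim = fin[["x"]], y_lim = fin[["y"]], z_lim = fin[["z"]],
               t_converge = tr$t_converge,
               stringsAsFactors = FALSE)
  }))
  conv <- runs[runs$outcome == "converged", c("x_lim", "y_lim", "z_lim")]
  consensus <- NULL
  if (nrow(conv) == nrow(runs) && nrow(conv) > 0L) {
    verts <- unique(round(as.matrix(conv)))
    if (nrow(verts) == 1L) consensus <- as.numeric(verts[1L, ])
  }
  list(runs = runs, tally = table(runs$outcome), consensus = consensus,
       seed = seed)
}

#' @export
print.care_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Replicator trajectory: %d samples, step %g, horizon %g\n",
              n, x$step, x$horizon))
  cat(sprintf("  start  (%.3f, %.3f, %.3f)\n", x$states[1L, 1L],
              x$states[1L, 2L], x$states[1L, 3L]))
  cat(sprintf("  final  (%.6f, %.6f, %.6f)\n", x$states[n, 1L],
              x$states[n, 2L], x$states[n, 3L]))
  if (identical(x$outcome, "converged"))
    cat(sprintf("  outcome: converged to (%d, %d, %d) by t = %g\n",
                x$vertex[1L], x$vertex[2L], x$vertex[3L], x$t_converge))
  else cat("  outcome:", x$outcome, "\n")
  invisible(x)
}

#' @export
plot.care_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "strategy probability",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("x (government)", "y (provider)",
                                       "z (older adults)"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}
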