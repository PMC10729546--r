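baseline <- anhui_baseline()

test_that("vertex starts stay put and the baseline midpoint reaches (1,1,1)", {
  tr_v <- integrate_trajectory(baseline, c(1, 0, 0), horizon = 5)
  expect_true(all(tr_v$states[, "x"] == 1))
  expect_true(all(tr_v$states[, "y"] == 0))
  expect_true(all(tr_v$states[, "z"] == 0))
  expect_identical(tr_v$outcome, "converged")
  expect_equal(tr_v$vertex, c(1, 0, 0))

  tr <- integrate_trajectory(baseline, c(0.5, 0.5, 0.5))
  expect_identical(tr$outcome, "converged")
  expect_equal(tr$vertex, c(1, 1, 1))

  tr2 <- integrate_trajectory(set_params(baseline, Nc = 10),
                              c(0.5, 0.5, 0.5))
  expect_equal(tr2$vertex, c(1, 0, 1))

  expect_error(integrate_trajectory(baseline, c(0.5, 0.5, 0.5), step = 0),
               "step")
  expect_error(integrate_trajectory(baseline, c(0.5, 0.5, 0.5),
                                    horizon = 0.001), "horizon")
})

test_that("integration agrees with an independent fixed-step solver", {
  skip_if_not_installed("deSolve")
  f <- function(t, s, parms) list(unname(replicator_rhs(parms, s)))
  sol <- deSolve::rk4(c(x = 0.5, y = 0.5, z = 0.5),
                      times = seq(0, 10, by = 0.01), func = f,
                      parms = baseline)
  tr <- integrate_trajectory(baseline, c(0.5, 0.5, 0.5), horizon = 10)
  expect_equal(unname(tr$states[nrow(tr$states), ]),
               unname(sol[nrow(sol), c("x", "y", "z")]), tolerance = 1e-8)
})

test_that("outcome detection separates convergence, cycling and drift", {
  const <- structure(
    list(times = seq(0, 1, length.out = 20L),
         states = matrix(rep(c(1, 1, 1), each = 20L), 20L, 3L,
                         dimnames = list(NULL, c("x", "y", "z")))),
    class = "care_trajectory")
  o <- detect_outcome(const)
  expect_identical(o$outcome, "converged")
  expect_equal(o$vertex, c(1, 1, 1))

  # regimes with no stable vertex keep oscillating
  for (p in list(set_params(baseline, Mg1 = 180),
                 set_params(baseline, Nc = 90))) {
    tr <- integrate_trajectory(p, c(0.5, 0.5, 0.5), horizon = 200)
    expect_identical(tr$outcome, "cyclic")
  }

  short <- structure(list(times = 0:5 / 5,
                          states = matrix(0.5, 6L, 3L)),
                     class = "care_trajectory")
  expect_error(detect_outcome(short), "10 samples")
})

test_that("initial-willingness sweeps reproduce the fixed-agent patterns", {
  # government fixed at 0.5, equal provider/older-adult starts: x -> 1
  sw <- initial_value_sweep(baseline, "x", 0.5, grid = c(0.1, 0.5, 0.9))
  expect_equal(nrow(sw$summary), 9L)
  expect_true(all(sw$summary$outcome == "converged"))
  expect_true(all(round(sw$summary$x_lim) == 1))

  # older adults fixed: z -> 1 for all (x0, y0) combinations
  sw_z <- initial_value_sweep(baseline, "z", 0.5, grid = c(0.2, 0.8))
  expect_true(all(round(sw_z$summary$z_lim) == 1))

  # a single-point grid equals the plain integration of that start
  sw1 <- initial_value_sweep(baseline, "x", 0.5, grid = 0.3)
  tr <- integrate_trajectory(baseline, c(0.5, 0.3, 0.3))
  expect_equal(sw1$trajectories[[1L]]$states, tr$states)

  expect_error(initial_value_sweep(baseline, "x", 0.5, grid = c(0, 0.5)),
               "strictly inside")
})

test_that("the randomized-start experiment is deterministic in its seed", {
  a <- replicate_convergence_experiment(baseline, n_runs = 5, seed = 7,
                                        horizon = 30)
  b <- replicate_convergence_experiment(baseline, n_runs = 5, seed = 7,
                                        horizon = 30)
  expect_identical(a$runs, b$runs)
  expect_identical(a$consensus, b$consensus)

  one <- replicate_convergence_experiment(baseline, n_runs = 1, seed = 7,
                                          horizon = 30)
  tr <- integrate_trajectory(baseline, sample_initial_states(1, seed = 7),
                             horizon = 30)
  expect_equal(one$runs$x_lim, tr$states[nrow(tr$states), "x"],
               ignore_attr = TRUE)
})

test_that("pre-projection overshoot respects the a priori step bound", {
  # with projected stages every stage slope is bounded by B/4, where B is
  # the largest payoff-difference bracket attainable on the cube, so a
  # single RK4 step can leave [0,1] by at most step * B / 4
  bracket_bound <- function(p) {
    b1 <- abs(p[["Sg1"]] - p[["Mg1"]] + p[["Mg2"]]) + p[["Lc1"]] +
      p[["Sg2"]] + p[["Ne"]] + p[["Nc"]]
    b2 <- abs(p[["Mc2"]] - p[["Mc1"]] - p[["c"]]) + p[["Nc"]] +
      p[["Lc1"]] + p[["Sc"]] + p[["Lc2"]]
    b3 <- abs(p[["Be"]] - p[["Me"]]) + p[["He1"]] + p[["He2"]] +
      p[["Lc2"]] + p[["Ne"]]
    max(b1, b2, b3)
  }
  ps <- random_params(50, seed = 111)
  init <- random_states(50, seed = 112, lo = 0.05, hi = 0.95)
  sim <- caregame:::.rk4_paths(caregame:::.param_matrix(ps), init,
                               step = 0.01, horizon = 30,
                               track_overshoot = TRUE)
  bound <- 0.01 * max(vapply(ps, bracket_bound, numeric(1L))) / 4
  expect_lte(sim$overshoot, bound)
  # and the post-projection trajectory is exactly inside the cube
  expect_true(all(sim$x >= 0 & sim$x <= 1))
  expect_true(all(sim$y >= 0 & sim$y <= 1))
  expect_true(all(sim$z >= 0 & sim$z <= 1))
})

test_that("halving the step never changes a converged vertex", {
  configs <- list(
    baseline,
    set_params(baseline, Nc = 10), set_params(baseline, Nc = 50),
    set_params(baseline, Lc1 = 250), set_params(baseline, Lc2 = 0),
    set_params(baseline, Me = 215), set_params(baseline, Be = 200),
    set_params(baseline, Ne = 10), set_params(baseline, Mg1 = 130),
    set_params(baseline, Sg1 = 350))
  for (p in configs) {
    t1 <- integrate_trajectory(p, c(0.5, 0.5, 0.5), horizon = 200,
                               step = 0.01)
    t2 <- integrate_trajectory(p, c(0.5, 0.5, 0.5), horizon = 200,
                               step = 0.005)
    expect_identical(t1$outcome, "converged")
    expect_identical(t2$outcome, "converged")
    expect_equal(t1$vertex, t2$vertex)
  }
})

test_that("simulation limits agree with the stability classification", {
  configs <- list(
    baseline,
    set_params(baseline, Nc = 10), set_params(baseline, Nc = 50),
    set_params(baseline, Lc1 = 250), set_params(baseline, Be = 200),
    set_params(baseline, Ne = 10), set_params(baseline, Mg1 = 130),
    set_params(baseline, Sg1 = 350))
  for (p in configs) {
    eq <- enumerate_equilibria(p)
    stable <- eq[eq$classification == "stable", c("x", "y", "z")]
    if (nrow(stable) != 1L) next
    tr <- integrate_trajectory(p, c(0.5, 0.5, 0.5), horizon = 200)
    expect_identical(tr$outcome, "converged")
    expect_equal(tr$vertex, unname(unlist(stable)))
  }
})
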