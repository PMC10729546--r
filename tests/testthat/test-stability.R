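baseline <- anhui_baseline()

test_that("baseline vertex eigenvalues match hand substitution", {
  expect_equal(vertex_eigenvalues(baseline, c(1, 1, 1)),
               c(lambda1 = -10, lambda2 = -50, lambda3 = -55))
  expect_equal(vertex_eigenvalues(baseline, c(1, 0, 0)),
               c(lambda1 = -235, lambda2 = -80, lambda3 = 45))
  expect_equal(vertex_eigenvalues(baseline, c(0, 0, 0)),
               c(lambda1 = 235, lambda2 = -160, lambda3 = -25))
  expect_error(vertex_eigenvalues(baseline, c(0.5, 0, 0)), "vertex")
})

test_that("the Jacobian is diagonal at vertices and its diagonal is the
           eigenvalue triple", {
  ps <- random_params(200, seed = 61)
  V <- cube_vertices()
  for (p in ps) {
    for (i in seq_len(nrow(V))) {
      J <- jacobian_at(p, V[i, ])
      expect_identical(J[row(J) != col(J)], rep(0, 6L))
      expect_identical(unname(diag(J)),
                       unname(vertex_eigenvalues(p, V[i, ])))
    }
  }
})

test_that("baseline Jacobian at (1,1,1) is diag(-10, -50, -55)", {
  expect_equal(unname(jacobian_at(baseline, c(1, 1, 1))),
               diag(c(-10, -50, -55)))
})

test_that("closed-form Jacobian agrees with central finite differences", {
  ps <- random_params(100, seed = 71)
  sts <- random_states(100, seed = 72, lo = 0.05, hi = 0.95)
  for (i in seq_along(ps)) {
    expect_equal(unname(jacobian_at(ps[[i]], sts[i, ])),
                 fd_jacobian(ps[[i]], sts[i, ]), tolerance = 1e-5)
  }
})

test_that("flipping one vertex coordinate exactly negates that eigenvalue", {
  ps <- random_params(50, seed = 81)
  V <- cube_vertices()
  for (p in ps) {
    for (i in seq_len(nrow(V))) {
      ev <- vertex_eigenvalues(p, V[i, ])
      for (k in 1:3) {
        w <- V[i, ]; w[k] <- 1 - w[k]
        expect_identical(ev[[k]] + vertex_eigenvalues(p, w)[[k]], 0)
      }
    }
  }
})

test_that("classification follows the Lyapunov first-method sign rule", {
  expect_identical(classify_vertex(c(-10, -50, -55)), "stable")
  expect_identical(classify_vertex(c(-235, -80, 45)), "unstable")
  expect_identical(classify_vertex(c(0, -1, -1)), "indeterminate")
  # trichotomy on random triples
  set.seed(91)
  for (i in 1:100) {
    e <- stats::runif(3, -5, 5) * sample(c(0, 1), 3, replace = TRUE)
    expect_true(classify_vertex(e) %in%
                  c("stable", "unstable", "indeterminate"))
  }
})

test_that("equilibrium enumeration finds the regime the parameters imply", {
  eq <- enumerate_equilibria(baseline)
  expect_equal(nrow(eq), 8L)
  expect_identical(eq$vertex[1L], "(0, 0, 0)")
  expect_identical(eq$vertex[8L], "(1, 1, 1)")
  expect_identical(eq$vertex[eq$classification == "stable"], "(1, 1, 1)")

  # costlier strict regulation: no stable vertex at all
  eq2 <- enumerate_equilibria(set_params(baseline, Mg1 = 180))
  expect_false(any(eq2$classification == "stable"))

  # weak provider reward: (1, 0, 1) becomes the unique attractor
  eq3 <- enumerate_equilibria(set_params(baseline, Nc = 10))
  expect_identical(eq3$vertex[eq3$classification == "stable"], "(1, 0, 1)")

  # removing compensation makes the provider direction degenerate at (1,1,1)
  eq4 <- enumerate_equilibria(set_params(baseline, Lc2 = 0))
  expect_identical(
    eq4$classification[eq4$vertex == "(1, 1, 1)"], "indeterminate")
})

test_that("scenario inequality systems match vertex stability", {
  chk <- check_scenario_conditions(baseline)
  expect_false(chk$scenario1$satisfied)
  expect_equal(chk$scenario1$lhs[3L], 45)
  expect_true(chk$scenario2$satisfied)
  expect_equal(chk$scenario2$lhs, c(-10, -50, -55))
  expect_false(chk$bistable)

  # dearer services: scenario 1 becomes satisfied too (bistable)
  chk2 <- check_scenario_conditions(set_params(baseline, Me = 215))
  expect_true(chk2$scenario1$satisfied)
  expect_equal(chk2$scenario1$lhs[3L], -5)
  expect_true(chk2$bistable)

  # agreement with enumerate_equilibria under tol = 0 semantics
  for (p in random_params(50, seed = 101)) {
    chk <- check_scenario_conditions(p)
    eq <- enumerate_equilibria(p)
    expect_identical(chk$scenario1$satisfied,
                     eq$classification[eq$vertex == "(1, 0, 0)"] == "stable")
    expect_identical(chk$scenario2$satisfied,
                     eq$classification[eq$vertex == "(1, 1, 1)"] == "stable")
  }
})
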