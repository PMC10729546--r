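# Independent oracles and random-case generators shared across the suite.

# Random valid parameter sets: uniform on the default ranges, rejecting
# draws that break the strict orderings.
random_params <- function(n, seed) {
  set.seed(seed)
  r <- default_ranges()
  lo <- vapply(r, `[`, numeric(1L), 1L)
  hi <- vapply(r, `[`, numeric(1L), 2L)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    draw <- stats::runif(length(lo), lo, hi)
    names(draw) <- names(lo)
    p <- tryCatch(validate_parameters(draw), error = function(e) NULL)
    if (!is.null(p)) {
      i <- i + 1L
      out[[i]] <- p
    }
  }
  out
}

random_states <- function(n, seed, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(stats::runif(3L * n, lo, hi), ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# Brute-force replicator field: enumerate the eight payoff cells, form the
# probability-weighted expected payoff of each pure strategy against the
# other agents' mixed play, and apply p(1-p)(payoff difference). This path
# goes through payoff_matrix() only, independent of the closed-form
# brackets in replicator_rhs().
brute_rhs <- function(params, state) {
  cells <- payoff_matrix(params)
  x <- state[[1L]]; y <- state[[2L]]; z <- state[[3L]]
  wg <- ifelse(cells$government == "strict", x, 1 - x)
  wp <- ifelse(cells$provider == "trustworthy", y, 1 - y)
  we <- ifelse(cells$elderly == "use", z, 1 - z)
  expect_strat <- function(payoff, own, lvl, w_others) {
    sum(payoff[cells[[own]] == lvl] * w_others[cells[[own]] == lvl])
  }
  G1 <- expect_strat(cells$gov_payoff, "government", "strict", wp * we)
  G2 <- expect_strat(cells$gov_payoff, "government", "relaxed", wp * we)
  C1 <- expect_strat(cells$prov_payoff, "provider", "trustworthy", wg * we)
  C2 <- expect_strat(cells$prov_payoff, "provider", "breach", wg * we)
  E1 <- expect_strat(cells$eld_payoff, "elderly", "use", wg * wp)
  E2 <- expect_strat(cells$eld_payoff, "elderly", "no_use", wg * wp)
  c(dx = x * (1 - x) * (G1 - G2),
    dy = y * (1 - y) * (C1 - C2),
    dz = z * (1 - z) * (E1 - E2))
}

# Central-difference Jacobian of replicator_rhs.
fd_jacobian <- function(params, state, h = 1e-6) {
  J <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    up <- state; up[j] <- state[j] + h
    dn <- state; dn[j] <- state[j] - h
    J[, j] <- (replicator_rhs(params, up) - replicator_rhs(params, dn)) /
      (2 * h)
  }
  J
}
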