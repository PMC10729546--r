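# Payoff matrix, expected payoffs and replicator right-hand side.

#' The tripartite payoff matrix
#'
#' The eight pure-strategy combinations of (government, provider, older
#' adults) and the payoff each agent receives in every cell. Older adults
#' who do not use the services receive exactly 0 in all four "no use"
#' cells.
#'
#' @param params a `"care_params"` vector (validated on entry).
#' @return A data frame with 8 rows and columns `government`
#'   (`"strict"`/`"relaxed"`), `provider` (`"trustworthy"`/`"breach"`),
#'   `elderly` (`"use"`/`"no_use"`), and numeric payoffs `gov_payoff`,
#'   `prov_payoff`, `eld_payoff`.
#' @export
#' @examples
#' payoff_matrix(anhui_baseline())
payoff_matrix <- function(params) {
  p <- validate_parameters(params)
  e <- function(nm) p[[nm]]
  cells <- expand.grid(
    government = c("strict", "relaxed"),
    provider   = c("trustworthy", "breach"),
    elderly    = c("use", "no_use"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  Mg1 <- e("Mg1"); Mg2 <- e("Mg2"); Sg1 <- e("Sg1"); Sg2 <- e("Sg2")
  Mc1 <- e("Mc1"); Mc2 <- e("Mc2"); Nc <- e("Nc"); Bc <- e("Bc")
  Sc <- e("Sc"); cc <- e("c"); Lc1 <- e("Lc1"); Lc2 <- e("Lc2")
  Me <- e("Me"); He1 <- e("He1"); He2 <- e("He2"); Ne <- e("Ne"); Be <- e("Be")

  pay <- function(g, pr, el) {
    if (el == "use") {
      if (g == "strict" && pr == "trustworthy")
        c(Sg1 - Mg1 - Bc - Be - Nc - Ne, Nc + Bc + Sc + Me - Mc1,
          Ne + Be + He1 - Me)
      else if (g == "relaxed" && pr == "trustworthy")
        c(-Mg2 - Bc - Be, Bc + Me + Sc - Mc1, Be + He1 - Me)
      else if (g == "strict")
        c(Sg1 + Lc1 - Mg1 - Bc - Be - Ne, Bc + cc + Me - Lc1 - Lc2 - Mc2,
          Lc2 + Ne + Be + He2 - Me)
      else
        c(-Mg2 - Bc - Be - Sg2, Bc + cc + Me - Mc2 - Lc2,
          Lc2 + Be + He2 - Me)
    } else {
      if (g == "strict" && pr == "trustworthy")
        c(Sg1 - Bc - Nc - Mg1, Nc + Bc - Mc1, 0)
      else if (g == "relaxed" && pr == "trustworthy")
        c(-Mg2 - Bc, Bc - Mc1, 0)
      else if (g == "strict")
        c(Sg1 + Lc1 - Mg1 - Bc, Bc + cc - Lc1 - Mc2, 0)
      else
        c(-Mg2 - Bc - Sg2, Bc + cc - Mc2, 0)
    }
  }
  m <- t(mapply(pay, cells$government, cells$provider, cells$elderly))
  cells$gov_payoff <- m[, 1L]
  cells$prov_payoff <- m[, 2L]
  cells$eld_payoff <- m[, 3L]
  rownames(cells) <- NULL
  cells
}

#' Expected payoffs of one agent
#'
#' For the requested agent, the expected payoff of its two pure strategies
#' against the mixed play of the other two agents, and its population mean
#' payoff. For the government these are G1 (strict), G2 (relaxed) and
#' Gbar = x G1 + (1-x) G2; analogously C1/C2/Cbar for the provider and
#' E1/E2/Ebar for older adults. A non-user interacts with nobody, so
#' E2 = 0 identically.
#'
#' @param params a `"care_params"` vector.
#' @param state probability triple (x, y, z), see [as_state()].
#' @param agent one of `"government"`, `"provider"`, `"elderly"`.
#' @return A list with elements `agent`, `s1` (strategy-1 expected payoff),
#'   `s0` (strategy-0 expected payoff) and `mean`.
#' @export
#' @examples
#' expected_payoffs(anhui_baseline(), c(0.5, 0.5, 0.5), "government")
expected_payoffs <- function(params, state,
                             agent = c("government", "provider", "elderly")) {
  p <- validate_parameters(params)
  s <- as_state(state)
  agent <- match.arg(agent)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  Mg1 <- p[["Mg1"]]; Mg2 <- p[["Mg2"]]; Sg1 <- p[["Sg1"]]; Sg2 <- p[["Sg2"]]
  Mc1 <- p[["Mc1"]]; Mc2 <- p[["Mc2"]]; Nc <- p[["Nc"]]; Bc <- p[["Bc"]]
  Sc <- p[["Sc"]]; cc <- p[["c"]]; Lc1 <- p[["Lc1"]]; Lc2 <- p[["Lc2"]]
  Me <- p[["Me"]]; He1 <- p[["He1"]]; He2 <- p[["He2"]]
  Ne <- p[["Ne"]]; Be <- p[["Be"]]

  if (agent == "government") {
    s1 <- z * y * (Sg1 - Mg1 - Bc - Be - Nc - Ne) +
      z * (1 - y) * (Sg1 + Lc1 - Mg1 - Bc - Be - Ne) +
      (1 - z) * y * (Sg1 - Bc - Nc - Mg1) +
      (1 - z) * (1 - y) * (Sg1 + Lc1 - Mg1 - Bc)
    s0 <- z * y * (-Mg2 - Bc - Be) +
      z * (1 - y) * (-Mg2 - Bc - Be - Sg2) +
      (1 - z) * y * (-Mg2 - Bc) +
      (1 - z) * (1 - y) * (-Mg2 - Bc - Sg2)
    mn <- x * s1 + (1 - x) * s0
  } else if (agent == "provider") {
    s1 <- z * x * (Nc + Bc + Sc + Me - Mc1) +
      z * (1 - x) * (Bc + Me + Sc - Mc1) +
      x * (1 - z) * (Nc + Bc - Mc1) +
      (1 - x) * (1 - z) * (Bc - Mc1)
    s0 <- z * x * (Bc + cc + Me - Lc1 - Lc2 - Mc2) +
      z * (1 - x) * (Bc + cc + Me - Mc2 - Lc2) +
      x * (1 - z) * (Bc + cc - Lc1 - Mc2) +
      (1 - x) * (1 - z) * (Bc + cc - Mc2)
    mn <- y * s1 + (1 - y) * s0
  } else {
    s1 <- x * y * (Ne + Be + He1 - Me) +
      y * (1 - x) * (Be + He1 - Me) +
      x * (1 - y) * (Lc2 + Ne + Be + He2 - Me) +
      (1 - x) * (1 - y) * (Lc2 + Be + He2 - Me)
    s0 <- 0
    mn <- z * s1 + (1 - z) * s0
  }
  list(agent = agent, s1 = s1, s0 = s0, mean = mn)
}

#' Replicator right-hand side
#'
#' The replication-dynamics vector field on the unit cube. Each agent's
#' cooperative-strategy frequency grows in proportion to that strategy's
#' advantage over the agent's mean payoff:
#' \deqn{dx/dt = x(1-x)[Sg1 + (1-y)Lc1 - Mg1 + Mg2 + (1-y)Sg2 - zNe - yNc]}
#' \deqn{dy/dt = y(1-y)[z(Sc+Lc2) + x(Nc+Lc1) - Mc1 - c + Mc2]}
#' \deqn{dz/dt = z(1-z)[yHe1 + xNe + (1-y)Lc2 + Be - Me + (1-y)He2]}
#' Every cube vertex is a fixed point, and the field does not depend on the
#' provider subsidy Bc.
#'
#' @inheritParams expected_payoffs
#' @return Named numeric vector `c(dx =, dy =, dz =)`.
#' @export
#' @examples
#' replicator_rhs(anhui_baseline(), c(0.5, 0.5, 0.5))
replicator_rhs <- function(params, state) {
  p <- validate_parameters(params)
  s <- as_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  b <- .rhs_brackets(p, x, y, z)
  c(dx = x * (1 - x) * b[["bx"]],
    dy = y * (1 - y) * b[["by"]],
    dz = z * (1 - z) * b[["bz"]])
}

# Payoff-difference brackets of the three replicator equations; vectorized
# over x, y, z (and over parameter columns when p is a matrix row-set).
#' @keywords internal
.rhs_brackets <- function(p, x, y, z) {
  list(
    bx = p[["Sg1"]] + (1 - y) * p[["Lc1"]] - p[["Mg1"]] + p[["Mg2"]] +
      (1 - y) * p[["Sg2"]] - z * p[["Ne"]] - y * p[["Nc"]],
    by = z * (p[["Sc"]] + p[["Lc2"]]) + x * (p[["Nc"]] + p[["Lc1"]]) -
      p[["Mc1"]] - p[["c"]] + p[["Mc2"]],
    bz = y * p[["He1"]] + x * p[["Ne"]] + (1 - y) * p[["Lc2"]] +
      p[["Be"]] - p[["Me"]] + (1 - y) * p[["He2"]])
}
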