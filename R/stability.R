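# Jacobian, vertex eigenvalues and Lyapunov first-method classification.

#' The eight pure-strategy equilibria of the unit cube
#'
#' Fixed ordering used in every report: (0,0,0), (0,0,1), (0,1,1), (0,1,0),
#' (1,0,0), (1,0,1), (1,1,0), (1,1,1).
#'
#' @return An 8 x 3 numeric matrix with columns x, y, z.
#' @export
cube_vertices <- function() {
  v <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0),
             c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  colnames(v) <- c("x", "y", "z")
  v
}

#' Jacobian of the replicator field
#'
#' Closed-form 3 x 3 Jacobian of [replicator_rhs()] at a state. Every
#' off-diagonal entry carries a p(1-p) factor of its row's probability, so
#' the Jacobian is exactly diagonal at any cube vertex.
#'
#' @inheritParams expected_payoffs
#' @return A 3 x 3 numeric matrix, rows/cols named (x, y, z).
#' @export
#' @examples
#' jacobian_at(anhui_baseline(), c(1, 1, 1))
jacobian_at <- function(params, state) {
  p <- validate_parameters(params)
  s <- as_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  b <- .rhs_brackets(p, x, y, z)
  J <- rbind(
    c((1 - 2 * x) * b$bx,
      x * (1 - x) * (-(p[["Lc1"]] + p[["Sg2"]] + p[["Nc"]])),
      x * (1 - x) * (-p[["Ne"]])),
    c(y * (1 - y) * (p[["Nc"]] + p[["Lc1"]]),
      (1 - 2 * y) * b$by,
      y * (1 - y) * (p[["Sc"]] + p[["Lc2"]])),
    c(z * (1 - z) * p[["Ne"]],
      z * (1 - z) * (p[["He1"]] - p[["He2"]] - p[["Lc2"]]),
      (1 - 2 * z) * b$bz))
  dimnames(J) <- list(c("x", "y", "z"), c("x", "y", "z"))
  J
}

#' Closed-form eigenvalues at a pure-strategy equilibrium
#'
#' At a cube vertex the Jacobian is diagonal and the eigenvalues are the
#' diagonal payoff-difference expressions, returned here from their closed
#' forms (no numeric eigendecomposition), in the (government, provider,
#' older-adult) direction order.
#'
#' @param params a `"care_params"` vector.
#' @param vertex length-3 vector of exact 0/1 coordinates.
#' @return Named numeric vector `c(lambda1 =, lambda2 =, lambda3 =)`.
#' @export
#' @examples
#' vertex_eigenvalues(anhui_baseline(), c(1, 1, 1))
vertex_eigenvalues <- function(params, vertex) {
  p <- validate_parameters(params)
  v <- unlist(vertex)
  if (length(v) != 3L || !all(v %in% c(0, 1)))
    stop("vertex must be a triple of exact 0/1 coordinates")
  x <- v[[1L]]; y <- v[[2L]]; z <- v[[3L]]
  # sign factor (1-2p) times the bracket evaluated at the vertex
  b <- .rhs_brackets(p, x, y, z)
  c(lambda1 = (1 - 2 * x) * b$bx,
    lambda2 = (1 - 2 * y) * b$by,
    lambda3 = (1 - 2 * z) * b$bz)
}

#' Lyapunov first-method classification of an eigenvalue triple
#'
#' All eigenvalues negative: the vertex is an evolutionarily stable
#' equilibrium ("stable"). Any positive eigenvalue: "unstable". A zero
#' eigenvalue with the rest negative: "indeterminate" (first-order analysis
#' cannot decide). `tol` separates "zero" from signed values; it defaults
#' to 1e-9 because parameters are exact user constants and near-zero
#' eigenvalues only arise from genuine degeneracy.
#'
#' @param eigs numeric length-3 vector of real eigenvalues.
#' @param tol non-negative zero threshold.
#' @return One of `"stable"`, `"unstable"`, `"indeterminate"`.
#' @export
#' @examples
#' classify_vertex(c(-10, -50, -55))
classify_vertex <- function(eigs, tol = 1e-9) {
  e <- as.numeric(unlist(eigs))
  if (length(e) != 3L || anyNA(e)) stop("eigs must be three real eigenvalues")
  if (any(e > tol)) return("unstable")
  if (all(e < -tol)) return("stable")
  "indeterminate"
}

#' Classify all eight pure-strategy equilibria
#'
#' Evaluates the closed-form eigenvalues at every cube vertex and applies
#' the Lyapunov first-method rule.
#'
#' @inheritParams vertex_eigenvalues
#' @param tol zero threshold passed to [classify_vertex()].
#' @return A data frame with one row per vertex (fixed ordering of
#'   [cube_vertices()]): columns `vertex` (label "(x, y, z)"), `x`, `y`,
#'   `z`, `lambda1`, `lambda2`, `lambda3`, `classification`.
#' @export
#' @examples
#' enumerate_equilibria(anhui_baseline())
enumerate_equilibria <- function(params, tol = 1e-9) {
  p <- validate_parameters(params)
  V <- cube_vertices()
  rows <- lapply(seq_len(nrow(V)), function(i) {
    ev <- vertex_eigenvalues(p, V[i, ])
    data.frame(
      vertex = sprintf("(%d, %d, %d)", V[i, 1L], V[i, 2L], V[i, 3L]),
      x = V[i, 1L], y = V[i, 2L], z = V[i, 3L],
      lambda1 = ev[["lambda1"]], lambda2 = ev[["lambda2"]],
      lambda3 = ev[["lambda3"]],
      classification = classify_vertex(ev, tol),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("care_equilibria", class(out))
  out
}

#' Stability conditions of the two policy scenarios
#'
#' Scenario 1: (1,0,0) — strict regulation, breach of trust, no use — is
#' evolutionarily stable when its three vertex eigenvalues are negative:
#' Mg1 - Sg1 - Lc1 - Mg2 - Sg2 < 0, Nc + Lc1 - Mc1 - c + Mc2 < 0 and
#' Ne + Lc2 + Be - Me + He2 < 0. Scenario 2: (1,1,1) — strict regulation,
#' trustworthy provider, use — is stable when Nc + Mg1 + Ne - Sg1 - Mg2 < 0,
#' Mc1 + c - Sc - Lc2 - Nc - Lc1 - Mc2 < 0 and Me - He1 - Ne - Be < 0.
#' Both systems can hold at once (a bistable regime, e.g. baseline with
#' Me = 215), which simulation then resolves by basin of attraction.
#'
#' @param params a `"care_params"` vector.
#' @return A list with entries `scenario1`, `scenario2`, each a list with
#'   `vertex`, `lhs` (the three inequality left-hand sides) and `satisfied`
#'   (all strictly negative); plus `bistable` (both satisfied).
#' @export
#' @examples
#' check_scenario_conditions(anhui_baseline())
check_scenario_conditions <- function(params) {
  p <- validate_parameters(params)
  l1 <- vertex_eigenvalues(p, c(1, 0, 0))
  l2 <- vertex_eigenvalues(p, c(1, 1, 1))
  s1 <- list(vertex = c(1, 0, 0), lhs = unname(l1), satisfied = all(l1 < 0))
  s2 <- list(vertex = c(1, 1, 1), lhs = unname(l2), satisfied = all(l2 < 0))
  list(scenario1 = s1, scenario2 = s2,
       bistable = s1$satisfied && s2$satisfied)
}
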