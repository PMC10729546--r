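#' @title Model parameters of the tripartite senior-care game
#' @description Constructors and validation for the 17 payoff parameters of
#'   the government / technology-service-provider / older-adult game. All
#'   payoffs are magnitudes in units of 10^4 CNY; the dynamics treat them as
#'   dimensionless reals.
#' @name care_params
NULL

#' Canonical parameter order used throughout the package.
#' @keywords internal
.param_names <- c(
  "Mg1", "Mg2", "Sg1", "Sg2",                        # government
  "Mc1", "Mc2", "Nc", "Bc", "Sc", "c", "Lc1", "Lc2", # provider
  "Me", "He1", "He2", "Ne", "Be"                     # older adults
)

#' Build a parameter set for the tripartite game
#'
#' Parameters (all non-negative, units 10^4 CNY):
#' \describe{
#'   \item{Mg1, Mg2}{cost of strict / relaxed government regulation
#'     (Mg1 > Mg2).}
#'   \item{Sg1}{benefit of strict regulation (credibility, performance).}
#'   \item{Sg2}{reputational loss when regulation is relaxed.}
#'   \item{Mc1, Mc2}{provider operating cost when trustworthy / in breach
#'     of trust (Mc1 > Mc2).}
#'   \item{Nc}{government reward to trustworthy providers.}
#'   \item{Bc}{government subsidy to providers. Not printed in the baseline
#'     source; defaults to 0. The replicator dynamics are provably invariant
#'     to Bc (it enters every cell of both provider rows and both government
#'     columns, so it cancels from every payoff difference).}
#'   \item{Sc}{brand/reputation gain of a trustworthy provider whose
#'     services are used.}
#'   \item{c}{additional benefit a provider extracts by breaching trust.}
#'   \item{Lc1}{government fine on a breaching provider under strict
#'     regulation.}
#'   \item{Lc2}{compensation a breaching provider pays to older adults.}
#'   \item{Me}{purchase cost of the services for older adults.}
#'   \item{He1, He2}{benefit to older adults using a trustworthy / breaching
#'     provider (He1 > He2).}
#'   \item{Ne}{government reward to older adults who use the services under
#'     strict regulation.}
#'   \item{Be}{government subsidy to older adults who use the services.}
#' }
#'
#' @param Mg1,Mg2,Sg1,Sg2,Mc1,Mc2,Nc,Bc,Sc,c,Lc1,Lc2,Me,He1,He2,Ne,Be numeric
#'   scalars as described above.
#' @return A named numeric vector of class `"care_params"`, validated.
#' @seealso [anhui_baseline()], [validate_parameters()], [set_params()]
#' @export
#' @examples
#' p <- anhui_baseline()
#' p[["Mc1"]]
care_params <- function(Mg1, Mg2, Sg1, Sg2, Mc1, Mc2, Nc, Bc = 0, Sc, c,
                        Lc1, Lc2, Me, He1, He2, Ne, Be) {
  p <- c(Mg1 = Mg1, Mg2 = Mg2, Sg1 = Sg1, Sg2 = Sg2,
         Mc1 = Mc1, Mc2 = Mc2, Nc = Nc, Bc = Bc, Sc = Sc, c = c,
         Lc1 = Lc1, Lc2 = Lc2,
         Me = Me, He1 = He1, He2 = He2, Ne = Ne, Be = Be)
  class(p) <- "care_params"
  validate_parameters(p)
}

#' The Anhui Province baseline parameter set
#'
#' The parameterisation derived from senior-care organisations and
#' regulations in Anhui Province, China (nursing-base operating costs,
#' provincial subsidy and fine schedules), used as the reference point of
#' every simulation and sensitivity sweep in this package. Bc, the subsidy
#' to providers, is not part of the printed values; it is set to 0 and the
#' dynamics do not depend on it.
#'
#' @return A validated `"care_params"` vector.
#' @export
#' @examples
#' anhui_baseline()
anhui_baseline <- function() {
  care_params(Mg1 = 150, Mg2 = 100, Sg1 = 200, Sg2 = 75,
              Mc1 = 135, Mc2 = 75, Nc = 70, Bc = 0, Sc = 80, c = 100,
              Lc1 = 10, Lc2 = 50,
              Me = 165, He1 = 120, He2 = 60, Ne = 70, Be = 30)
}

#' Validate a parameter set
#'
#' Checks that all 17 fields are present, finite and non-negative and that
#' the three strict cost/benefit orderings hold: Mg1 > Mg2, Mc1 > Mc2,
#' He1 > He2. Orderings are checked exactly (no tolerance): parameters are
#' user-specified constants, not estimates.
#'
#' @param params object coercible to `"care_params"` (named numeric vector
#'   or list with the 17 parameter names).
#' @return The validated `"care_params"` vector, unchanged.
#' @export
validate_parameters <- function(params) {
  p <- unlist(params)
  missing <- setdiff(.param_names, names(p))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(p), .param_names)
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- p[.param_names]
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop("all parameters must be finite numerics")
  if (any(p < 0)) {
    bad <- names(p)[which(p < 0)[1L]]
    stop("non-negativity violated: ", bad, " < 0")
  }
  if (!(p[["Mg1"]] > p[["Mg2"]])) stop("ordering Mg1 > Mg2 violated")
  if (!(p[["Mc1"]] > p[["Mc2"]])) stop("ordering Mc1 > Mc2 violated")
  if (!(p[["He1"]] > p[["He2"]])) stop("ordering He1 > He2 violated")
  class(p) <- "care_params"
  p
}

#' Modify fields of a parameter set
#'
#' One-at-a-time perturbations from a baseline, re-validated. This is the
#' primitive behind [sweep_parameter()].
#'
#' @param params a `"care_params"` vector.
#' @param ... named scalar replacements, e.g. `Nc = 10`.
#' @return A validated `"care_params"` vector.
#' @export
#' @examples
#' set_params(anhui_baseline(), Nc = 10)
set_params <- function(params, ...) {
  p <- validate_parameters(params)
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("replacements must be named")
  unknown <- setdiff(names(repl), .param_names)
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- unlist(repl)
  validate_parameters(p)
}

#' Validate a strategy state on the unit cube
#'
#' A state is the probability triple (x, y, z): x = P(government plays
#' strict regulation), y = P(provider is trustworthy), z = P(older adults
#' use the services). Boundary values are legal (needed for vertex
#' analysis).
#'
#' @param state numeric length-3 vector, optionally named.
#' @return A named numeric vector `c(x =, y =, z =)`.
#' @export
as_state <- function(state) {
  s <- unlist(state)
  if (length(s) != 3L || !is.numeric(s) || anyNA(s))
    stop("state must be three numeric probabilities (x, y, z)")
  if (any(s < 0) || any(s > 1))
    stop("state coordinates must lie in [0, 1]")
  s <- as.numeric(s)
  names(s) <- c("x", "y", "z")
  s
}

#' @export
print.care_params <- function(x, ...) {
  cat("Tripartite senior-care game parameters (10^4 CNY):\n")
  print(unclass(x), ...)
  invisible(x)
}
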