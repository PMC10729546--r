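# Scenario sampler: random parameter sets with a prescribed stability
# regime, and random interior initial states. All randomness in the
# package flows through the seeds taken here.

#' Default parameter sampling ranges
#'
#' Each parameter uniform on 0.5x to 1.5x its Anhui baseline value, which
#' keeps draws in the empirically grounded magnitude regime; Bc (absent
#' from the baseline, and irrelevant to the dynamics) on [0, 100].
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_ranges <- function() {
  base <- unclass(anhui_baseline())
  r <- lapply(names(base), function(nm) {
    if (nm == "Bc") c(0, 100) else base[[nm]] * c(0.5, 1.5)
  })
  names(r) <- names(base)
  r
}

#' Specify a sampling scenario
#'
#' @param regime target stability regime of the sampled parameter sets:
#'   `"unconstrained"` (any valid set), `"scenario1"` ((1,0,0) stable:
#'   strict regulation, breach, no use), `"scenario2"` ((1,1,1) stable:
#'   strict regulation, trustworthy, use) or `"cyclic"` (no stable
#'   vertex).
#' @param ranges named list of per-parameter uniform ranges (default
#'   [default_ranges()]).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling cap (default 10000).
#' @param allow_bistable for `"scenario1"`/`"scenario2"`: keep draws where
#'   the other scenario's vertex is simultaneously stable (they are tagged
#'   `bistable`); set `FALSE` to reject them.
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(regime = c("unconstrained", "scenario1",
                                     "scenario2", "cyclic"),
                          ranges = default_ranges(), seed = 42,
                          max_attempts = 10000, allow_bistable = TRUE) {
  regime <- match.arg(regime)
  missing <- setdiff(.param_names, names(ranges))
  if (length(missing) > 0L)
    stop("ranges missing for: ", paste(missing, collapse = ", "))
  for (nm in .param_names) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(r < 0) || r[2L] < r[1L])
      stop("invalid range for ", nm)
  }
  structure(list(regime = regime, ranges = ranges, seed = seed,
                 max_attempts = max_attempts,
                 allow_bistable = allow_bistable),
            class = "scenario_spec")
}

#' Rejection-sample a parameter set in a target regime
#'
#' Draws each parameter uniformly within its range and rejects until the
#' draw is a valid parameter set (non-negativity and strict orderings) in
#' the requested regime: for scenario 1 / scenario 2 the three vertex
#' eigenvalues of (1,0,0) / (1,1,1) are all negative; for `"cyclic"` no
#' vertex is stable. Reproducible for a fixed seed.
#'
#' @param spec a `"scenario_spec"`.
#' @return A validated `"care_params"` vector with attributes `regime`,
#'   `bistable` (both scenario systems hold) and `attempts` (number of
#'   draws used).
#' @export
#' @examples
#' p <- sample_parameters(scenario_spec("scenario2", seed = 1))
#' attr(p, "bistable")
sample_parameters <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  set.seed(spec$seed)
  lo <- vapply(spec$ranges[.param_names], `[`, numeric(1L), 1L)
  hi <- vapply(spec$ranges[.param_names], `[`, numeric(1L), 2L)
  for (attempt in seq_len(spec$max_attempts)) {
    draw <- stats::runif(length(.param_names), lo, hi)
    names(draw) <- .param_names
    p <- tryCatch(validate_parameters(draw), error = function(e) NULL)
    if (is.null(p)) next
    chk <- check_scenario_conditions(p)
    keep <- switch(spec$regime,
      unconstrained = TRUE,
      scenario1 = chk$scenario1$satisfied &&
        (spec$allow_bistable || !chk$scenario2$satisfied),
      scenario2 = chk$scenario2$satisfied &&
        (spec$allow_bistable || !chk$scenario1$satisfied),
      cyclic = {
        eq <- enumerate_equilibria(p)
        !any(eq$classification == "stable")
      })
    if (keep) {
      attr(p, "regime") <- spec$regime
      attr(p, "bistable") <- chk$bistable
      attr(p, "attempts") <- attempt
      return(p)
    }
  }
  stop("failed to sample a '", spec$regime, "' parameter set in ",
       spec$max_attempts, " attempts")
}

#' Random interior initial states
#'
#' `n` strategy triples drawn uniformly on (0.05, 0.95)^3, the
#' randomized-start distribution of the repeated-evolution experiment.
#'
#' @param n number of states (>= 1).
#' @param seed RNG seed.
#' @return An n x 3 matrix with columns x, y, z.
#' @export
#' @examples
#' sample_initial_states(3, seed = 1)
sample_initial_states <- function(n, seed = 42) {
  if (!is.numeric(n) || n < 1L) stop("n must be at least 1")
  n <- as.integer(n)
  set.seed(seed)
  m <- matrix(stats::runif(3L * n, 0.05, 0.95), nrow = n, ncol = 3L,
              byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}
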