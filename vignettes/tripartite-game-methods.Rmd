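---
title: "Methods: replicator dynamics and stability analysis of the smart senior-care game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicator dynamics and stability analysis of the smart senior-care game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caregame)
```

## The game and its assumptions

Smart senior-care services are delivered by technology providers, paid
for by older adults, and regulated by a government. Each party has two
strategies — the government regulates strictly or loosely (probability
`x` of strict), providers deliver trustworthy service or breach trust
(probability `y`), older adults use the services or stay away
(probability `z`). Payoffs for every pure-strategy combination are
linear combinations of 17 non-negative parameters (costs, rewards,
subsidies, fines, compensation, benefits), with three structural
orderings: strict regulation costs more than relaxed (`Mg1 > Mg2`),
trustworthy operation costs more than breaching (`Mc1 > Mc2`), and a
trustworthy provider benefits its users more (`He1 > He2`). Older
adults who do not use the services interact with nobody and receive
exactly zero.

The behavioural premise is bounded rationality: no agent jumps to a
best response; instead each strategy's frequency grows in proportion to
its payoff advantage over the agent's current mean payoff. That yields
the replicator system `dp/dt = p(1-p) * (payoff difference)` for each of
the three probabilities, a vector field on the unit cube whose payoff
differences are affine in the other two agents' probabilities (see
`replicator_rhs()`). Two consequences shape everything downstream:

* every cube vertex is a fixed point, exactly;
* the provider subsidy `Bc` cancels from every payoff difference (it is
  paid in all cells of both provider rows and both government columns),
  so the dynamics are invariant to it. `Bc` is kept as a parameter for
  completeness — its baseline value is not part of the published
  parameterisation, and we default it to 0.

Mixed-strategy (interior) equilibria are deliberately out of scope: in
asymmetric games an evolutionarily stable profile must be a strict Nash
equilibrium, hence a pure-strategy vertex, so the package only ever
classifies the eight vertices.

## Stability classification

The Jacobian of the field has closed-form entries; every off-diagonal
entry carries a `p(1-p)` factor of its row's own probability, so at a
vertex the matrix is diagonal and its eigenvalues are the diagonal
payoff-difference expressions. `vertex_eigenvalues()` evaluates those
closed forms directly — no numerical eigendecomposition — which keeps
the stability table exact for exact parameter inputs; the numerical
Jacobian path exists only as a finite-difference cross-check in the test
suite. Classification follows the Lyapunov first method: all eigenvalues
negative means asymptotically stable (an ESS), any positive eigenvalue
means unstable, and a zero eigenvalue with the rest negative is reported
as `indeterminate` because the linearisation cannot decide.

Two useful structural facts, both tested exactly:

* **Flip antisymmetry.** No payoff-difference bracket depends on the
  agent's own probability, so flipping one coordinate of a vertex
  exactly negates the corresponding eigenvalue. Adjacent vertices can
  therefore never both be stable.
* **Scenario systems.** The stability conditions of (1,0,0) ("strict
  regulation, breach, no use" — scenario 1) and of (1,1,1) ("strict
  regulation, trustworthy, use" — scenario 2) are the inequality systems
  checked by `check_scenario_conditions()`; they are literally the
  statements that the three vertex eigenvalues are negative. Both can
  hold at once (e.g. the baseline with `Me = 215`), a bistable regime in
  which only simulation can say which attractor a given start reaches.

**Zero tolerance.** Eigenvalues are compared against `tol = 1e-9`.
Parameters are exact user-supplied constants, so a zero eigenvalue
arises only from genuine structural degeneracy (for instance `Lc2 = 0`
makes the provider direction at (1,1,1) exactly neutral at the
baseline); `1e-9` merely guards against floating-point noise in
composite expressions and is far below any payoff scale of interest.

## Numerical integration

Trajectories are integrated with classic fixed-step fourth-order
Runge–Kutta, step `0.01`, horizon `100` (or `200` when probing possibly
cyclic regimes). A fixed step keeps runs bit-reproducible across
platforms and makes the repeated-run experiments exactly seed-determined.

The state space is the closed unit cube, and the integrator enforces
that by projection — including at the internal RK4 stages, not only at
the end of a step. Stage projection matters at this model's payoff
magnitudes: payoff-difference brackets reach several hundred per unit
time, so an unprojected half-step can leave the cube, where the
quadratic factor `p(1-p)` changes sign and pushes the stage derivative
the wrong way. Concretely, with `Lc1 = 250` an unprojected fixed-step
integration at step 0.01 freezes the provider probability near 0.81 — a
spurious fixed point of the discrete map — whereas the projected scheme
converges to (1,1,1) as the eigenvalue analysis requires, and halving
the step does not change any converged vertex. With projected stages
every stage slope is bounded by `B/4`, where `B` is the largest bracket
magnitude attainable on the cube, so a step can overshoot the cube by at
most `step * B / 4`; the overshoot is transient (order `1e-4` at the
baseline) and removed by the final projection.

**Outcome classification.** A trajectory is *converged* to vertex `v`
when its sup-norm distance to `v` (the componentwise rounding of its
final state) stays below `conv_tol = 1e-3` throughout the final 10% of
samples; otherwise it is *cyclic* when at least one coordinate still
ranges over more than `cycle_amp = 0.05` during the final 50% of the
horizon; otherwise *not converged*. At the model's payoff scales these
defaults separate the two observed behaviours by orders of magnitude —
converged runs settle within `1e-12` while cycling regimes oscillate
with amplitude well above 0.1 — so the classification is insensitive to
the exact thresholds. The `not_converged` label is reserved for genuine
degeneracies: with `c = 150` the provider direction on the edge
`x = z = 1` is exactly neutral, the edge is a continuum of equilibria,
and the trajectory converges to (1, 0.06, 1) — a point, but not a
vertex. The sweep tables therefore report the limiting coordinates as
well as the outcome label, and the sensitivity conclusions for that row
rest on the provider's limiting probability (0.06, the breach side), not
on the vertex label.

## Experiments

* **Repeated evolution** (`replicate_convergence_experiment()`): `n`
  initial states drawn uniformly from `(0.05, 0.95)^3` under one seed,
  integrated and tallied, reporting the consensus vertex when all runs
  agree. We read the published "evolving the array 50 times" as 50
  randomized initial conditions; neither a 50-unit horizon nor 50
  iterations of anything else produces a meaningful experiment, and the
  randomized reading is the one the consensus check makes precise.
* **Initial-willingness grids** (`initial_value_sweep()`): one
  coordinate fixed at 0.5, the other two on a grid in (0,1), matching
  the published construction. Grid points on the boundary are rejected
  because vertex-degenerate starts never move.
* **Sensitivity sweeps** (`sweep_parameter()`): one parameter replaced
  at a time, all else at the Anhui baseline, integrated from
  (0.5, 0.5, 0.5) — the fixed value used throughout the
  initial-willingness construction; the published sensitivity figures do
  not state their start, so the midpoint is our choice, not an assertion
  about theirs. Each row records the outcome, the limiting coordinates,
  and two convergence times: the sup-norm time for the whole state and
  the focal agent's own settling time. The qualitative speed claims
  (larger fines or subsidies accelerate the focal agent) hold for the
  focal coordinate's time; the whole-state time can move the other way
  because another agent becomes the bottleneck.

## The scenario sampler and what passing tests show

`sample_parameters()` draws each parameter uniformly on 0.5–1.5 times
its baseline value (`Bc` on [0, 100]) and rejects draws until the
requested regime holds: the scenario-1 or scenario-2 inequalities, or
(for `"cyclic"`) no stable vertex at all. Draws satisfying both scenario
systems are tagged `bistable` rather than rejected. The ranges keep
draws in the magnitude regime of the empirical parameterisation; they
emulate plausible policy variation, not an empirical distribution, and
carry no correlation structure between parameters.

One caveat the test suite makes explicit: local stability of a vertex
does not make it globally attracting. For non-bistable scenario-2 draws
the flip-antisymmetry structure rules out every competing stable vertex
and, empirically, all draws flow from the midpoint to (1,1,1). For
scenario-1 draws a minority (about 6% under the default ranges) either
cycles despite (1,0,0) being the unique stable vertex or reaches a
coexisting stable vertex such as (0,1,1). The tests therefore assert
what is true — converged runs always end at an eigenvalue-stable vertex,
and (1,0,0) is the majority limit — rather than universal convergence.
Passing these tests shows internal consistency between the analytic and
simulated routes under the stated conditions; it says nothing about how
real governance systems off this payoff structure behave.

## Problem sizes and determinism

The shipped experiments use 50 randomized starts for the repeated-run
experiment, 81-point initial-value grids, and 43 sensitivity runs over
nine parameters; a single trajectory is 10,000–20,000 RK4 steps. The
only randomness anywhere is the drawing of initial states and of sampled
parameter sets, each governed by a single integer seed, so every table
in `results/` is byte-reproducible from (config, seed).

## Known limitations

* Fixed-step RK4 has no error control; the step-halving invariance test
  stands in for it at the model's payoff scales. Payoffs orders of
  magnitude above the baseline would need a smaller step.
* The cycle label is operational (sustained amplitude above
  `cycle_amp`), not a proof of a limit cycle; slow non-convergence and
  genuine cycling are distinguished only as far as the horizon sees.
* Indeterminate (zero-eigenvalue) vertices are reported, not resolved;
  no centre-manifold analysis is attempted.
* Parameters are treated as exact constants; there is no calibration,
  uncertainty propagation, or currency handling beyond the 10^4 CNY
  unit convention.
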