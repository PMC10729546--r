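# caregame

An R package for modelling the governance of **smart senior care** —
technology-mediated elder-care services delivered through internet/IoT
platforms — as an asymmetric tripartite evolutionary game between

* a **government** choosing *strict* or *relaxed* regulation (probability
  `x` of strict),
* **technology service providers** choosing *trustworthy* service or
  *breach of trust* (probability `y` of trustworthy), and
* **older adults** choosing to *use* or *not use* the services
  (probability `z` of use).

It is aimed at health-systems and policy researchers who want a tested,
reproducible implementation of the model's payoff structure, stability
analysis and simulation experiments, rather than one-off scripts.

## The model

Agents are boundedly rational: strategy frequencies evolve by replicator
dynamics, where each probability grows in proportion to that strategy's
payoff advantage over the agent's mean payoff. With the 17 payoff
parameters (regulation costs `Mg1 > Mg2`, regulation benefit `Sg1`,
reputation loss `Sg2`, provider costs `Mc1 > Mc2`, reward `Nc`, subsidy
`Bc`, brand gain `Sc`, breach benefit `c`, fine `Lc1`, compensation
`Lc2`, service price `Me`, user benefits `He1 > He2`, user reward `Ne`
and user subsidy `Be`), the system is

    dx/dt = x(1-x) [ Sg1 + (1-y)Lc1 - Mg1 + Mg2 + (1-y)Sg2 - zNe - yNc ]
    dy/dt = y(1-y) [ z(Sc+Lc2) + x(Nc+Lc1) - Mc1 - c + Mc2 ]
    dz/dt = z(1-z) [ yHe1 + xNe + (1-y)Lc2 + Be - Me + (1-y)He2 ]

The eight cube vertices (pure-strategy profiles) are fixed points; each
is classified with the **Lyapunov first method** from the closed-form
eigenvalues of the Jacobian, which is diagonal at every vertex. Two
inequality systems characterise the policy-relevant attractors: scenario
1 makes (1,0,0) — strict regulation, breach, no use — stable, scenario 2
makes (1,1,1) — strict regulation, trustworthy, use — stable. The
dynamics are provably independent of the provider subsidy `Bc`.

Trajectories are integrated with fixed-step fourth-order Runge–Kutta
(step 0.01) with all stage and step states projected onto the unit cube,
and classified as converged to a vertex, cyclic, or not converged.

## Worked example

```r
library(caregame)

baseline <- anhui_baseline()      # parameterisation from Anhui Province
enumerate_equilibria(baseline)[, c("vertex", "lambda1", "lambda2",
                                   "lambda3", "classification")]
#>       vertex lambda1 lambda2 lambda3 classification
#> x  (0, 0, 0)     235    -160     -25       unstable
#> x1 (0, 0, 1)     165     -30      25       unstable
#> x2 (0, 1, 1)      10      30      15       unstable
#> x3 (0, 1, 0)      80     160     -15       unstable
#> x4 (1, 0, 0)    -235     -80      45       unstable
#> x5 (1, 0, 1)    -165      50     -45       unstable
#> x6 (1, 1, 0)     -80      80      55       unstable
#> x7 (1, 1, 1)     -10     -50     -55         stable
```

(1,1,1) is the unique evolutionarily stable point: all three of its
eigenvalues are negative, so strict regulation, trustworthy provision
and uptake by older adults reinforce each other. Simulation agrees:

```r
ex <- replicate_convergence_experiment(baseline, n_runs = 50, seed = 42)
ex$tally
#> converged
#>        50
ex$consensus
#> [1] 1 1 1
```

and a one-at-a-time sweep shows how the consensus collapses when the
reward to trustworthy providers is cut, or cycles when it is pushed too
high:

```r
sweep_parameter(baseline, "Nc", c(10, 50, 90))[, c("parameter", "value",
                                                   "outcome", "y_lim")]
#>   parameter value   outcome y_lim
#> 1        Nc    10 converged     0
#> 2        Nc    50 converged     1
#> 3        Nc    90    cyclic     1
```

The numbered scripts under `analysis/` run the full set of experiments
(stability table, 50-run baseline experiment, initial-willingness grids,
all sensitivity sweeps) and write their tables under `results/`.

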