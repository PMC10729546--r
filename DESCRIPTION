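Package: caregame
Title: Tripartite Evolutionary Game of Smart Senior-Care Governance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Replicator-dynamics model of the governance of smart
    (technology-mediated) senior-care services as an asymmetric
    three-player evolutionary game between a government (strict versus
    relaxed regulation), technology service providers (trustworthy versus
    breach of trust) and older adults (use versus no use). Provides the
    tripartite payoff matrix, expected payoffs and replicator equations;
    closed-form Jacobian and vertex eigenvalues with Lyapunov
    first-method classification of the eight pure-strategy equilibria;
    a projected fixed-step Runge-Kutta integrator on the unit cube with
    convergence and cycle detection; one-at-a-time parameter sensitivity
    sweeps; and a scenario sampler that draws parameter sets satisfying
    the inequality systems under which (1,0,0) or (1,1,1) is
    evolutionarily stable. Ships the Anhui Province baseline
    parameterisation used throughout the analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
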