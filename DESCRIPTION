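Package: epiMaster
Title: Master-Equation Analysis of Stochastic Compartmental Epidemic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact probabilistic analysis of stochastic SIS and SIR epidemic
    dynamics through the Doi-Peliti (occupation-number) representation of the
    master equation. Enumerates the configuration basis of each compartmental
    model, assembles the sparse transition-rate generator, and propagates full
    probability distributions over outbreak trajectories with the
    matrix-exponential propagator. Provides deterministic ODE baselines and
    the final-size relation, marginal distributions and Shannon-entropy
    summaries of forecast uncertainty, branching-process (Whittle) extinction
    probabilities with their recursion and closed form, tau-leap and exact
    event-driven stochastic simulation with minor-outbreak classification,
    and a forecast-conditioning experiment quantifying how uncertainty about
    the epidemic peak depends on when forecasts are issued.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
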