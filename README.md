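# epiMaster

Master-equation analysis of stochastic compartmental epidemic models.

Deterministic SIS/SIR equations track only the *expected* occupation of
each compartment. The stochastic dynamics underneath them — contagion at
rate βSI/N, recovery at rate γI in a closed, well-mixed population of N
individuals — is a continuous-time Markov chain over occupation-number
configurations, and its master equation

    d/dt P(x, t) = Σ_x′ H_{x,x′} P(x′, t)

propagates the *full probability distribution* over outbreak
trajectories. `epiMaster` builds the configuration basis of each model
(I = 0..N for SIS; pairs (S, I) with S + I ≤ N for SIR), assembles the
sparse rate generator H, and evolves the state with the exponential
propagator e^{HΔt}. From the propagated distribution it extracts the
observables that deterministic models cannot see:

* **bimodal outcome clouds** — the coexistence of minor (stochastically
  extinguished) and major outbreaks for R0 > 1;
* **no-outbreak probabilities** — the mass of the steady-state recovered
  marginal below the minor-outbreak bound, checked against the
  branching-process (Whittle) recursion and its closed form
  π_NO(I0) = (1/R0)^{I0} for R0 > 1 (1 otherwise);
* **forecast uncertainty** — the Shannon entropy H = −Σ P log P of the
  infected marginal, and how the uncertainty about the epidemic peak
  depends on the time at which a forecast is conditioned on data.

Deterministic ODE baselines (closed-form SIS logistic, high-accuracy SIR
integration, the implicit final-size relation), τ-leap and exact
event-driven simulation complete the toolkit, so every quantity can be
computed by at least two independent routes. The intended users are
infectious-disease modellers and teachers of stochastic epidemic theory
working at populations up to a few thousand (SIS) or a few hundred
(SIR), where the full distribution is tractable.

## Worked example

Probability that a pathogen with R0 = 2 seeded by one case in N = 100
individuals fails to cause an outbreak — by three routes:

```r
library(epiMaster)

params <- paramsFromR0(2, N = 100, model = "SIR")

## 1. branching-process closed form
whittleClosedForm(2, 1)
#> [1] 0.5

## 2. master equation: steady-state recovered marginal below the
##    minor-outbreak bound (20% of the deterministic attack rate + I0)
gen <- buildGenerator(params)
steady <- steadyStateDistribution(gen, deltaState(gen@space, S = 99, I = 1))
noOutbreakMass(marginalRecovered(steady), minorOutbreakBound(params, 1))
#> [1] 0.5172569

## 3. tau-leap simulation at N = 10000 (1000 runs)
big <- paramsFromR0(2, N = 1e4, model = "SIR")
est <- estimateNoOutbreak(big, 1, simulationConfig(nRuns = 1000, baseSeed = 42))
est$fraction
#> [1] 0.503
```

The three estimates agree: the closed form gives exactly 1/R0 = 0.5, the
master equation at N = 100 carries a small finite-population excess
(0.517), and the simulation estimate (0.503) sits within its binomial
confidence interval of both.

The forecast-conditioning experiment quantifies when an epidemic peak
becomes predictable:

```r
res <- runForecastStudy(forecastConfig(r0List = 6, N = 100))
head(res@summary[, c("r0", "dtilde0", "peakEntropy", "dtildeHmax")], 3)
#>   r0 dtilde0 peakEntropy dtildeHmax
#> 1  6   -1.00    3.558560 -0.2941176
#> 2  6   -0.95    3.634888 -0.2441176
#> 3  6   -0.90    3.664479 -0.2882353
```

`peakEntropy` is the entropy (nats) of the infected marginal at the
deterministic peak when forecasts are conditioned at relative time
`dtilde0` (−1 = outbreak start, 0 = the peak); it rises to an interior
maximum and drops to 0 at `dtilde0 = 0`. `dtildeHmax < 0` says the
moment of maximal uncertainty precedes the peak.

A thin command-line front end over the same functions lives at
`inst/scripts/epimaster.R` (subcommands `propagate`, `deterministic`,
`extinction`, `simulate`, `forecast`, `cloud`, `fixtures`; see the
script header for flags and the YAML configuration schema in
`?readRunConfig`).

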