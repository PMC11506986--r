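#' Stochastic-simulation settings
#'
#' @param tau leap duration for the tau-leap algorithm; default 0.05
#'   (small enough that leap-induced bias is below Monte Carlo noise in
#'   the convergence study of the methods vignette).
#' @param nRuns ensemble size; default 1000.
#' @param baseSeed base random seed; default 1.
#' @param maxTime hard cap on simulated time per run; default 1000.
#' @param exact use the exact event-driven algorithm instead of leaping.
#' @return validated settings list (class `"SimulationConfig"`).
#' @export
simulationConfig <- function(tau = 0.05, nRuns = 1000L, baseSeed = 1L,
                             maxTime = 1000, exact = FALSE) {
  stopifnot(tau > 0, nRuns >= 1L, maxTime > 0)
  structure(list(tau = tau, nRuns = as.integer(nRuns),
                 baseSeed = as.integer(baseSeed), maxTime = maxTime,
                 exact = isTRUE(exact)),
            class = "SimulationConfig")
}

#' Minor-outbreak classification rule
#'
#' @param fraction threshold multiplier in (0, 1); default 0.2 of the
#'   deterministic attack rate (`R0 > 1`) or of the population
#'   (`R0 <= 1`), plus the seed count.
#' @return list of class `"MinorOutbreakRule"`.
#' @export
minorOutbreakRule <- function(fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  structure(list(fraction = fraction), class = "MinorOutbreakRule")
}

withSeed <- function(seed, expr) {
  force(seed)  # must precede the state snapshot below
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Single tau-leap SIR run
#'
#' Simulates one SIR outbreak with fixed leaps of length `tau`: per
#' leap, contagion and recovery event counts are Poisson with means
#' `beta S I tau / N` and `gamma I tau` (rates frozen at the leap
#' start), capped at the available individuals with contagion applied
#' before recovery.  The run ends when `I = 0` or `maxTime` is reached.
#' Seeding by `baseSeed + runIndex` makes runs individually
#' reproducible and embarrassingly parallel.
#'
#' @param params an [EpidemicParams-class] (model `"SIR"`).
#' @param i0 seed count (>= 1).
#' @param config a [simulationConfig()].
#' @param runIndex run number used for seeding; default 1.
#' @return list with `attack` (final recovered count), `extinctTime`
#'   (or `NA` if `maxTime` was hit) and `seed`.
#' @export
tauLeapRun <- function(params, i0, config = simulationConfig(),
                       runIndex = 1L) {
  stopifnot(is(params, "EpidemicParams"), params@model == "SIR", i0 >= 1)
  seed <- config$baseSeed + as.integer(runIndex)
  withSeed(seed, {
    n <- params@N
    tau <- config$tau
    S <- n - i0; I <- i0; R <- 0L
    t <- 0
    extinctTime <- NA_real_
    while (I > 0L && t < config$maxTime) {
      nC <- min(stats::rpois(1L, params@beta * S * I * tau / n), S)
      nR <- min(stats::rpois(1L, params@gamma * I * tau), I + nC)
      S <- S - nC
      I <- I + nC - nR
      R <- R + nR
      t <- t + tau
      if (I == 0L) extinctTime <- t
    }
    list(attack = R, extinctTime = extinctTime, seed = seed)
  })
}

#' Vectorized tau-leap SIR ensemble
#'
#' Runs `nRuns` tau-leap trajectories simultaneously, advancing all
#' active runs one leap at a time with vectorized Poisson draws.  The
#' ensemble is deterministic given `baseSeed` (a single RNG stream
#' shared across runs).  With `earlyStopR` set, a run is retired as soon
#' as its recovered count reaches the threshold; its recorded attack is
#' then censored at that value (sufficient for minor/major
#' classification, which only asks whether the threshold was crossed).
#'
#' @param params an [EpidemicParams-class] (model `"SIR"`).
#' @param i0 seed count (>= 1).
#' @param config a [simulationConfig()].
#' @param earlyStopR optional recovered-count threshold for early
#'   retirement of major-outbreak runs.
#' @return data.frame with columns `run`, `attack`, `censored`.
#' @export
tauLeapEnsemble <- function(params, i0, config = simulationConfig(),
                            earlyStopR = NULL) {
  stopifnot(is(params, "EpidemicParams"), params@model == "SIR", i0 >= 1)
  withSeed(config$baseSeed, {
    n <- params@N
    tau <- config$tau
    nr <- config$nRuns
    S <- rep.int(n - i0, nr); I <- rep.int(as.integer(i0), nr)
    R <- integer(nr)
    active <- rep.int(TRUE, nr)
    censored <- rep.int(FALSE, nr)
    t <- 0
    while (any(active) && t < config$maxTime) {
      idx <- which(active)
      nC <- pmin(stats::rpois(length(idx),
                              params@beta * S[idx] * I[idx] * tau / n),
                 S[idx])
      newI <- I[idx] + nC
      nR <- pmin(stats::rpois(length(idx), params@gamma * I[idx] * tau), newI)
      S[idx] <- S[idx] - nC
      I[idx] <- newI - nR
      R[idx] <- R[idx] + nR
      done <- I[idx] == 0L
      if (!is.null(earlyStopR)) {
        hit <- R[idx] >= earlyStopR & !done
        censored[idx[hit]] <- TRUE
        done <- done | hit
      }
      active[idx[done]] <- FALSE
      t <- t + tau
    }
    data.frame(run = seq_len(nr), attack = R, censored = censored)
  })
}

#' Exact event-driven stochastic run
#'
#' Statistically exact simulation of the two reactions (contagion at
#' rate `beta S I / N`, recovery at rate `gamma I`) by drawing
#' exponential waiting times from the total rate and picking the event
#' proportionally to its propensity — the direct stochastic simulation
#' algorithm, used as the arbiter for both the tau-leap approximation
#' and the master-equation marginals.
#'
#' @param params an [EpidemicParams-class] (`"SIS"` or `"SIR"`).
#' @param i0 seed count (>= 1).
#' @param seed random seed for this run.
#' @param maxTime stop time; default 1000.
#' @return data.frame with columns `time`, `S`, `I`, `R` (post-event
#'   states, first row the initial condition; `R` is 0 throughout for
#'   SIS).
#' @export
exactEventRun <- function(params, i0, seed, maxTime = 1000) {
  stopifnot(is(params, "EpidemicParams"), i0 >= 1)
  withSeed(seed, {
    n <- params@N
    sis <- params@model == "SIS"
    cap <- 256L
    times <- numeric(cap); Ss <- integer(cap); Is <- integer(cap)
    Rs <- integer(cap)
    S <- n - as.integer(i0); I <- as.integer(i0); R <- 0L
    t <- 0
    k <- 1L
    times[1L] <- 0; Ss[1L] <- S; Is[1L] <- I; Rs[1L] <- R
    while (I > 0L) {
      rateC <- params@beta * S * I / n
      rateR <- params@gamma * I
      total <- rateC + rateR
      t <- t + stats::rexp(1L, total)
      if (t > maxTime) break
      if (stats::runif(1L) * total < rateC) {
        S <- S - 1L; I <- I + 1L
      } else {
        I <- I - 1L
        if (sis) S <- S + 1L else R <- R + 1L
      }
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(times) <- cap; length(Ss) <- cap; length(Is) <- cap
        length(Rs) <- cap
      }
      times[k] <- t; Ss[k] <- S; Is[k] <- I; Rs[k] <- R
    }
    data.frame(time = times[1:k], S = Ss[1:k], I = Is[1:k], R = Rs[1:k])
  })
}

#' Ensemble of exact runs sampled at one time
#'
#' Runs `n` exact event-driven simulations (seeded `baseSeed + run`) and
#' returns the infected count of each at time `t`; the empirical
#' histogram of these counts is the Monte Carlo reference for the
#' master-equation marginal.
#'
#' @param params an [EpidemicParams-class].
#' @param i0 seed count.
#' @param n number of runs.
#' @param t sampling time.
#' @param baseSeed base seed.
#' @return integer vector of infected counts, one per run.
#' @export
exactEnsembleAtTime <- function(params, i0, n, t, baseSeed = 1L) {
  vapply(seq_len(n), function(run) {
    withSeed(baseSeed + run, {
      nn <- params@N
      sis <- params@model == "SIS"
      S <- nn - as.integer(i0); I <- as.integer(i0)
      tt <- 0
      while (I > 0L) {
        rateC <- params@beta * S * I / nn
        total <- rateC + params@gamma * I
        tt <- tt + stats::rexp(1L, total)
        if (tt > t) break
        if (stats::runif(1L) * total < rateC) {
          S <- S - 1L; I <- I + 1L
        } else {
          I <- I - 1L
          if (sis) S <- S + 1L
        }
      }
      I
    })
  }, integer(1L))
}

#' Classify an attack rate as a minor outbreak
#'
#' Applies the minor-outbreak rule: an attack rate (final recovered
#' count) at or below `fraction * R_det + i0` (for `R0 > 1`, with
#' `R_det` the deterministic attack rate) or `fraction * N + i0` (for
#' `R0 <= 1`) is a minor outbreak.
#'
#' @param attack final recovered count(s); vectorized.
#' @param params an [EpidemicParams-class].
#' @param i0 seed count.
#' @param rule a [minorOutbreakRule()].
#' @param deterministicAttack deterministic attack-rate count, required
#'   when `R0 > 1`.
#' @return logical vector.
#' @export
classifyMinor <- function(attack, params, i0, rule = minorOutbreakRule(),
                          deterministicAttack = NULL) {
  r0 <- basicReproduction(params)
  if (r0 > 1 && is.null(deterministicAttack))
    stop("'deterministicAttack' is required when R0 > 1")
  bound <- minorOutbreakBound(params, i0, fraction = rule$fraction,
                              deterministicAttack = deterministicAttack)
  attack <= bound
}

#' No-outbreak fraction of an ensemble
#'
#' Fraction of runs classified as minor outbreaks, with an exact
#' binomial confidence interval.
#'
#' @param minor logical vector of minor-outbreak flags.
#' @param conf confidence level; default 0.95.
#' @return list with `fraction`, `ciLow`, `ciHigh`, `n`.
#' @export
noOutbreakFraction <- function(minor, conf = 0.95) {
  stopifnot(is.logical(minor), length(minor) >= 1L)
  k <- sum(minor)
  n <- length(minor)
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  list(fraction = k / n, ciLow = ci[1L], ciHigh = ci[2L], n = n)
}

#' Simulated no-outbreak probability for one scenario
#'
#' End-to-end estimate of the no-outbreak probability by tau-leap
#' simulation: computes the deterministic attack rate, runs the
#' ensemble (retiring runs early once they provably exceed the minor
#' bound), classifies each run, and reports the minor fraction next to
#' the branching-process closed form.
#'
#' @param params an [EpidemicParams-class] (model `"SIR"`).
#' @param i0 seed count.
#' @param config a [simulationConfig()].
#' @param rule a [minorOutbreakRule()].
#' @return list with `fraction`, `ciLow`, `ciHigh`, `n`, `whittle`,
#'   `bound`.
#' @export
estimateNoOutbreak <- function(params, i0, config = simulationConfig(),
                               rule = minorOutbreakRule()) {
  r0 <- basicReproduction(params)
  detAttack <- if (r0 > 1)
    params@N * sirFinalSize(r0, s0 = (params@N - i0) / params@N) else NULL
  bound <- minorOutbreakBound(params, i0, fraction = rule$fraction,
                              deterministicAttack = detAttack)
  ens <- tauLeapEnsemble(params, i0, config, earlyStopR = floor(bound) + 1L)
  minor <- classifyMinor(ens$attack, params, i0, rule, detAttack)
  est <- noOutbreakFraction(minor)
  c(est, list(whittle = whittleClosedForm(r0, i0), bound = bound))
}
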