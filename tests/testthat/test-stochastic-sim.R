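test_that("degenerate simulations follow their closed forms", {
  # no transmission: every seed recovers and nobody else is infected
  par0 <- epidemicParams(0, 0.1, 100, "SIR")
  for (k in 1:5)
    expect_equal(tauLeapRun(par0, 5, simulationConfig(maxTime = 500),
                            runIndex = k)$attack, 5)
  # exact simulator, no transmission: waiting times are exponential and
  # the run ends after exactly i0 recoveries
  tr <- exactEventRun(par0, 4, seed = 3)
  expect_equal(nrow(tr), 5L)
  expect_equal(tail(tr$R, 1), 4L)
  expect_equal(tail(tr$I, 1), 0L)
})

test_that("runs are reproducible from their seeds", {
  par <- paramsFromR0(2, 200, "SIR")
  cfg <- simulationConfig(nRuns = 30L, baseSeed = 17L)
  a <- tauLeapRun(par, 1, cfg, runIndex = 4L)
  b <- tauLeapRun(par, 1, cfg, runIndex = 4L)
  expect_identical(a, b)
  e1 <- tauLeapEnsemble(par, 1, cfg)
  e2 <- tauLeapEnsemble(par, 1, cfg)
  expect_identical(e1, e2)
  expect_identical(exactEventRun(par, 1, seed = 5),
                   exactEventRun(par, 1, seed = 5))
})

test_that("subcritical outbreaks always go extinct", {
  par <- paramsFromR0(0.5, 50, "SIS")
  ext <- vapply(1:300, function(k) {
    tr <- exactEventRun(par, 1, seed = k, maxTime = 5000)
    tail(tr$I, 1) == 0L
  }, logical(1))
  expect_true(all(ext))
})

test_that("exact simulation matches the master-equation marginal", {
  par <- paramsFromR0(3, 15, "SIS")
  gen <- buildGenerator(par)
  ser <- evolveState(gen, deltaState(gen@space, I = 1),
                     propagationConfig(dt = 0.1, tMax = 8,
                                       recordStride = 80L))
  dp <- marginalInfected(seriesState(ser))@probs
  counts <- exactEnsembleAtTime(par, 1, 1500, 8, baseSeed = 23L)
  emp <- empiricalPmf(counts, 15)
  bound <- 3 * sqrt(log(2 * 16) / (2 * 1500))
  expect_lt(totalVariation(emp, dp), bound)
})

test_that("tau-leap converges in distribution to the exact simulator", {
  # bias at the default leap sizes is below Monte Carlo resolution, so
  # the convergence sweep starts from deliberately coarse leaps where
  # the Poisson-clipping bias is visible
  par <- paramsFromR0(2, 500, "SIR")
  exact <- vapply(1:2000, function(k)
    tail(exactEventRun(par, 1, seed = 1000 + k, maxTime = 1000)$R, 1),
    integer(1))
  brks <- c(-0.5, seq(9.5, 489.5, by = 20), 500.5)
  pe <- hist(exact, breaks = brks, plot = FALSE)$counts / 2000
  tv <- vapply(c(4, 1, 0.2, 0.05), function(tau) {
    ens <- tauLeapEnsemble(par, 1, simulationConfig(
      tau = tau, nRuns = 2000L, baseSeed = 5L, maxTime = 1000))
    ph <- hist(ens$attack, breaks = brks, plot = FALSE)$counts / 2000
    totalVariation(ph, pe)
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[4], 0.04)
})

test_that("minor-outbreak classification follows both rule branches", {
  parSub <- paramsFromR0(0.5, 100, "SIR")
  # R0 < 1 branch: threshold 0.2 N + i0 = 21
  expect_true(classifyMinor(10, parSub, 1))
  expect_true(classifyMinor(21, parSub, 1))
  expect_false(classifyMinor(22, parSub, 1))
  parSup <- paramsFromR0(3, 100, "SIR")
  det <- 100 * sirFinalSize(3, 0.99)
  expect_error(classifyMinor(10, parSup, 1), "deterministicAttack")
  expect_false(classifyMinor(100, parSup, 1, deterministicAttack = det))
  # immediate extinction is minor under every rule
  expect_true(classifyMinor(1, parSup, 1, minorOutbreakRule(0.05),
                            deterministicAttack = det))
})

test_that("no-outbreak fractions behave at the extremes", {
  allMinor <- noOutbreakFraction(rep(TRUE, 50))
  expect_equal(allMinor$fraction, 1)
  noneMinor <- noOutbreakFraction(rep(FALSE, 50))
  expect_equal(noneMinor$fraction, 0)
  mixed <- noOutbreakFraction(rep(c(TRUE, FALSE), 50))
  expect_true(mixed$ciLow < 0.5 && mixed$ciHigh > 0.5)
})

test_that("simulated no-outbreak fractions match the branching law", {
  par <- paramsFromR0(3, 5000, "SIR")
  est <- estimateNoOutbreak(par, 1, simulationConfig(nRuns = 800L,
                                                     baseSeed = 2L))
  se <- sqrt(est$whittle * (1 - est$whittle) / est$n)
  expect_lt(abs(est$fraction - est$whittle), 3 * se)
})

test_that("estimates are insensitive to the minor-outbreak fraction", {
  for (r0 in c(1.5, 3)) {
    par <- paramsFromR0(r0, 1e4, "SIR")
    cfg <- simulationConfig(nRuns = 1000L, baseSeed = 11L)
    f20 <- estimateNoOutbreak(par, 1, cfg, minorOutbreakRule(0.2))$fraction
    f05 <- estimateNoOutbreak(par, 1, cfg, minorOutbreakRule(0.05))$fraction
    expect_lt(abs(f20 - f05), 0.02)
  }
})
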