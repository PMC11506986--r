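refTrajectory <- function(r0, n, i0 = 1L, tEnd = 300) {
  params <- paramsFromR0(r0, n, "SIR")
  solveSirOde(params, s0 = 1 - i0 / n, i0 = i0 / n, r0 = 0,
              tGrid = seq(0, tEnd, by = 0.01))
}

test_that("conditioning rounds fractions to a valid delta state", {
  sp <- buildStateSpace(epidemicParams(0.6, 0.1, 100, "SIR"))
  traj <- refTrajectory(6, 100)
  p0 <- conditionOnTrajectory(traj, 0, sp)
  expect_equal(p0@probs[stateIndex(sp, S = 99, I = 1)], 1)
  expect_equal(sum(p0@probs), 1)
  expect_equal(sum(p0@probs > 0), 1L)
  expect_error(conditionOnTrajectory(traj, 1e5, sp), "span")

  # nearest-integer rule on a synthetic trajectory with known fractions
  params <- paramsFromR0(6, 100, "SIR")
  fake <- new("DeterministicTrajectory", model = "SIR", times = c(0, 1),
              fractions = matrix(rep(c(0.554, 0.278, 0.168), 2), 2,
                                 byrow = TRUE,
                                 dimnames = list(NULL, c("s", "i", "r"))),
              params = params)
  pF <- conditionOnTrajectory(fake, 0.5, sp)
  expect_equal(pF@probs[stateIndex(sp, S = 55, I = 28)], 1)

  # repair when rounding pushes S + I above N: S is decremented first
  fake2 <- new("DeterministicTrajectory", model = "SIR", times = c(0, 1),
               fractions = matrix(rep(c(0.505, 0.495, 0), 2), 2,
                                  byrow = TRUE,
                                  dimnames = list(NULL, c("s", "i", "r"))),
               params = params)
  pR <- conditionOnTrajectory(fake2, 0, sp)
  expect_equal(pR@probs[stateIndex(sp, S = 50, I = 50)], 1)
})

test_that("relative offsets are computed against the peak", {
  expect_equal(relativeTimes(10, 10, 12)$dtilde0, 0)
  expect_equal(relativeTimes(0, 10, 12)$dtilde0, -1)
  expect_equal(relativeTimes(5, 10, 8)$dtildeHmax, -0.2)
  expect_error(relativeTimes(1, 0, 1), "tPeak")
})

test_that("conditioning at the peak gives zero peak entropy", {
  n <- 50L
  traj <- refTrajectory(4, n)
  gen <- buildGenerator(paramsFromR0(4, n, "SIR"))
  pk <- peakTime(traj)
  expect_equal(peakEntropy(gen, traj, pk$time), 0)
  expect_gt(peakEntropy(gen, traj, pk$time / 2), 0)
})

test_that("early conditioning retains the no-outbreak atom, late loses it", {
  n <- 100L
  r0 <- 6
  params <- paramsFromR0(r0, n, "SIR")
  gen <- buildGenerator(params)
  traj <- refTrajectory(r0, n)
  pk <- peakTime(traj)
  bound <- minorOutbreakBound(params, 1)
  atomMass <- function(t0) {
    p0 <- conditionOnTrajectory(traj, t0, gen@space)
    ser <- evolveState(gen, p0, propagationConfig(
      dt = 0.1, tMax = pk$time - t0, recordStride = 10000L))
    m <- marginalInfected(seriesState(ser))
    sum(m@probs[m@support <= bound])
  }
  expect_gte(atomMass(0), 0.5 * (1 / r0))
  expect_lt(atomMass(pk$time / 2), 0.01)
})

test_that("the forecast study reproduces the uncertainty profile", {
  res <- runForecastStudy(forecastConfig(
    r0List = 4, N = 50L, relTimes = seq(-1, 0, length.out = 9L)),
    keepSeries = TRUE)
  s <- res@summary
  expect_false(any(s$noPeak))
  # entropy at the peak vanishes when conditioning at the peak
  expect_equal(s$peakEntropy[nrow(s)], 0)
  # interior maximum of the peak-entropy curve
  imax <- which.max(s$peakEntropy)
  expect_gt(imax, 1L)
  expect_lt(imax, nrow(s))
  # monotone decay after the interior maximum
  expect_true(all(diff(s$peakEntropy[imax:nrow(s)]) <= 1e-9))
  # maximum uncertainty precedes the peak for early conditioning
  expect_lt(s$dtildeHmax[1L], 0)
  # entropy series are finite and bounded by log(N + 1)
  for (ent in res@series)
    expect_true(all(is.finite(ent$entropy) & ent$entropy >= 0 &
                      ent$entropy <= log(51)))
})

test_that("scenarios without a deterministic peak are flagged", {
  res <- runForecastStudy(forecastConfig(
    r0List = 0.8, N = 30L, relTimes = c(-1, -0.5, 0)), keepSeries = FALSE)
  expect_true(all(res@summary$noPeak))
  expect_true(all(is.na(res@summary$peakEntropy)))
})
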