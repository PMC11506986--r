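test_that("delta states put unit mass on the requested configuration", {
  sp <- buildStateSpace(epidemicParams(0.6, 0.1, 3, "SIS"))
  p <- deltaState(sp, I = 2)
  expect_equal(p@probs, c(0, 0, 1, 0))
  sp1 <- buildStateSpace(epidemicParams(0.6, 0.1, 1, "SIR"))
  p1 <- deltaState(sp1, S = 0, I = 0)
  expect_equal(sum(p1@probs), 1)
  expect_equal(p1@probs[stateIndex(sp1, S = 0, I = 0)], 1)
  expect_error(deltaState(sp, I = 7), "range")
})

test_that("absorbing states are fixed points of the propagator", {
  gen <- buildGenerator(epidemicParams(0.9, 0.2, 8, "SIS"))
  p0 <- deltaState(gen@space, I = 0)
  expect_equal(stepState(gen, p0, dt = 3)@probs, p0@probs)
})

test_that("pure-death chains follow their closed forms", {
  # N=1 SIR: single recovery clock, P(I=1)(t) = exp(-gamma t)
  gen <- buildGenerator(epidemicParams(0.6, 0.1, 1, "SIR"))
  p1 <- stepState(gen, deltaState(gen@space, S = 0, I = 1), dt = 1)
  expect_equal(p1@probs[stateIndex(gen@space, S = 0, I = 1)], exp(-0.1),
               tolerance = 1e-10)

  # N=2 SIR without transmission: two independent recovery clocks, the
  # infected marginal is binomial(2, exp(-gamma t))
  gen2 <- buildGenerator(epidemicParams(0, 0.25, 2, "SIR"))
  ser <- evolveState(gen2, deltaState(gen2@space, S = 0, I = 2),
                     propagationConfig(dt = 0.5, tMax = 4))
  for (tt in c(1, 2.5, 4)) {
    m <- marginalInfected(seriesState(ser, time = tt))
    expect_equal(m@probs, dbinom(0:2, 2, exp(-0.25 * tt)),
                 tolerance = 1e-9)
  }
})

test_that("dense and uniformization paths agree with an independent expm", {
  set.seed(99)
  for (rep in 1:6) {
    params <- randomParams(nMax = 20L)
    gen <- buildGenerator(params)
    sp <- gen@space
    p0 <- if (params@model == "SIS") deltaState(sp, I = 1)
          else deltaState(sp, S = params@N - 1L, I = 1)
    tEnd <- 4
    cfgD <- propagationConfig(dt = 0.5, tMax = tEnd, recordStride = 8L,
                              method = "dense")
    cfgU <- propagationConfig(dt = 0.5, tMax = tEnd, recordStride = 8L,
                              method = "uniformization")
    vD <- seriesState(evolveState(gen, p0, cfgD))@probs
    vU <- seriesState(evolveState(gen, p0, cfgU))@probs
    vO <- drop(expmOracle(as.matrix(generatorMatrix(gen)) * tEnd) %*%
                 p0@probs)
    expect_lt(max(abs(vD - vO)), 1e-8)
    expect_lt(max(abs(vU - vO)), 1e-8)
  }
})

test_that("the propagator has the semigroup property", {
  set.seed(7)
  for (rep in 1:5) {
    params <- randomParams(nMax = 15L)
    gen <- buildGenerator(params)
    sp <- gen@space
    p0 <- if (params@model == "SIS") deltaState(sp, I = min(2L, params@N))
          else deltaState(sp, S = params@N - 1L, I = 1)
    dt <- runif(1, 0.05, 0.5)
    twice <- stepState(gen, stepState(gen, p0, dt), dt)
    once <- stepState(gen, p0, 2 * dt)
    expect_lt(max(abs(twice@probs - once@probs)), 1e-8)
  }
})

test_that("mass is conserved and SIS absorption is monotone", {
  gen <- buildGenerator(epidemicParams(0.45, 0.15, 25, "SIS"))
  ser <- evolveState(gen, deltaState(gen@space, I = 1),
                     propagationConfig(dt = 0.1, tMax = 40,
                                       recordStride = 10L))
  expect_lt(max(abs(colSums(ser@probs) - 1)), 1e-9)
  pAbs <- ser@probs[1L, ]
  expect_true(all(diff(pAbs) >= -1e-12))
})

test_that("a zero horizon returns only the initial state", {
  gen <- buildGenerator(epidemicParams(0.3, 0.1, 5, "SIS"))
  p0 <- deltaState(gen@space, I = 2)
  ser <- evolveState(gen, p0, propagationConfig(dt = 0.1, tMax = 0))
  expect_equal(length(ser@times), 1L)
  expect_equal(ser@probs[, 1L], p0@probs)
})

test_that("steady-state search reaches the SIS absorbing state", {
  gen <- buildGenerator(epidemicParams(0.3, 0.2, 12, "SIS"))
  ss <- steadyStateDistribution(gen, deltaState(gen@space, I = 2),
                                dt = 1, tMax = 5000)
  expect_true(attr(ss, "converged"))
  expect_gt(ss@probs[1L], 1 - 1e-6)
})
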