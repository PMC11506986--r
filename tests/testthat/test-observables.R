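sirUniform <- function(n) {
  sp <- buildStateSpace(epidemicParams(0.6, 0.1, n, "SIR"))
  new("ProbabilityVector", probs = rep(1 / nStates(sp), nStates(sp)),
      time = 0, space = sp)
}

test_that("marginals sum the joint state correctly", {
  sp <- buildStateSpace(epidemicParams(0.6, 0.1, 2, "SIR"))
  d <- deltaState(sp, S = 1, I = 1)
  expect_equal(marginalInfected(d)@probs, c(0, 1, 0))
  expect_equal(marginalRecovered(deltaState(sp, S = 0, I = 0))@probs,
               c(0, 0, 1))
  # uniform over the 6 states of N=2: count states per I (3, 2, 1 for
  # I = 0, 1, 2) and per R (R = 2 - S - I, so R = 0 is the S + I = 2
  # anti-diagonal with 3 states, down to 1 state at R = 2)
  u <- sirUniform(2)
  expect_equal(marginalInfected(u)@probs, c(3, 2, 1) / 6)
  expect_equal(marginalRecovered(u)@probs, c(3, 2, 1) / 6)
  expect_equal(sum(marginalInfected(u)@probs), 1)
  # SIS states pass through unchanged
  spS <- buildStateSpace(epidemicParams(0.6, 0.1, 4, "SIS"))
  pS <- deltaState(spS, I = 3)
  expect_equal(marginalInfected(pS)@probs, pS@probs)
  expect_error(marginalRecovered(pS), "SIR")
})

test_that("entropy follows its conventions and bounds", {
  expect_equal(shannonEntropy(c(0, 1, 0)), 0)
  expect_equal(shannonEntropy(rep(1 / 7, 7)), log(7))
  expect_equal(shannonEntropy(rep(1 / 8, 8), base = 2), 3)
  # bounds hold on every snapshot of a propagated series
  gen <- buildGenerator(epidemicParams(0.8, 0.1, 20, "SIS"))
  ser <- evolveState(gen, deltaState(gen@space, I = 1),
                     propagationConfig(dt = 0.1, tMax = 30,
                                       recordStride = 20L))
  h <- entropySeries(ser, "I")$entropy
  expect_true(all(h >= 0 & h <= log(21)))
})

test_that("expected fractions match closed-form means", {
  sp <- buildStateSpace(epidemicParams(0.6, 0.1, 10, "SIS"))
  expect_equal(expectedFraction(marginalInfected(deltaState(sp, I = 7))),
               0.7)
  u <- new("MarginalDistribution", compartment = "I", support = 0:10,
           probs = rep(1 / 11, 11), time = 0)
  expect_equal(expectedFraction(u), 1 / 2)
  b <- new("MarginalDistribution", compartment = "I", support = 0:10,
           probs = dbinom(0:10, 10, 0.3), time = 0)
  expect_equal(expectedFraction(b), 0.3)
})

test_that("no-outbreak mass integrates the low-attack region", {
  u <- marginalRecovered(sirUniform(2))
  expect_equal(noOutbreakMass(u, 2), 1)
  expect_equal(noOutbreakMass(u, 0), 3 / 6)
  expect_error(noOutbreakMass(u, -1), ">= 0")
  d <- new("MarginalDistribution", compartment = "R", support = 0:5,
           probs = c(1, 0, 0, 0, 0, 0), time = 0)
  expect_equal(noOutbreakMass(d, 0), 1)
})

test_that("steady SIR recovered marginals are bimodal above threshold", {
  # R0 well above 1 with a single seed: mass both in the minor-outbreak
  # window and around the deterministic attack rate
  n <- 60L
  params <- paramsFromR0(4, n, "SIR")
  gen <- buildGenerator(params)
  ss <- steadyStateDistribution(gen, deltaState(gen@space, S = n - 1L,
                                                I = 1),
                                method = "uniformization")
  mr <- marginalRecovered(ss)
  bound <- minorOutbreakBound(params, 1)
  attack <- n * sirFinalSize(4, (n - 1) / n)
  major <- sum(mr@probs[mr@support >= 0.8 * attack &
                          mr@support <= 1.2 * attack])
  expect_gte(noOutbreakMass(mr, bound), 0.5 * (1 / 4))
  expect_gte(major, 0.5 * (1 - 1 / 4))
})

test_that("order-parameter clouds track the deterministic values", {
  # SIS metastable mode near (1 - 1/R0) N at reduced scale
  cl <- orderParameterCloud("SIS", 4, N = 60L, i0 = 1L)
  mode <- cl$cloud$count[-1][which.max(cl$cloud$probability[-1])]
  expect_lt(abs(mode - 0.75 * 60), 6)
  # SIR: no-outbreak mass approaches 1 as R0 -> 0
  lowR0 <- paramsFromR0(0.2, 40, "SIR")
  gen <- buildGenerator(lowR0)
  ss <- steadyStateDistribution(gen, deltaState(gen@space, S = 39, I = 1),
                                method = "uniformization")
  expect_gt(noOutbreakMass(marginalRecovered(ss),
                           minorOutbreakBound(lowR0, 1)), 0.98)
})

test_that("SIR entropy is non-monotonic in R0 near the threshold", {
  res <- orderParameterCloud("SIR", c(0.8, 1.4, 3.5), N = 40L, i0 = 1L)
  h <- res$entropy$entropy
  expect_gt(h[2], h[1])
  expect_gt(h[2], h[3])
})
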