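setMethod("marginalInfected", "ProbabilityVector", function(p, ...) {
  sp <- p@space
  n <- sp@N
  if (sp@model == "SIS") {
    probs <- p@probs
  } else {
    probs <- as.numeric(
      rowsum(p@probs, group = sp@labels[, "I"], reorder = TRUE))
  }
  new("MarginalDistribution", compartment = "I", support = 0:n,
      probs = probs, time = p@time)
})

setMethod("marginalRecovered", "ProbabilityVector", function(p, ...) {
  sp <- p@space
  if (sp@model != "SIR")
    stop("the recovered marginal is only defined for SIR state spaces")
  n <- sp@N
  r <- n - sp@labels[, "S"] - sp@labels[, "I"]
  probs <- as.numeric(rowsum(p@probs, group = r, reorder = TRUE))
  new("MarginalDistribution", compartment = "R", support = 0:n,
      probs = probs, time = p@time)
})

setMethod("show", "MarginalDistribution", function(object) {
  cat(sprintf(
    "MarginalDistribution (%s) at t = %g: support 0..%d, mean = %.4g\n",
    object@compartment, object@time, max(object@support),
    sum(object@support * object@probs)))
})

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum P(X) log P(X)` with the convention `0 log 0 = 0`; natural
#' logarithm by default.  `H` is 0 for a point mass and `log(M)` for a
#' uniform distribution over `M` points, the bounds of forecast
#' uncertainty used throughout.
#'
#' @param dist a [MarginalDistribution-class] or a normalized numeric
#'   vector of probabilities.
#' @param base logarithm base; default `exp(1)` (nats).
#' @return numeric(1), the entropy.
#' @examples
#' shannonEntropy(c(1, 0, 0))       # 0
#' shannonEntropy(rep(1 / 4, 4))    # log(4)
#' @export
shannonEntropy <- function(dist, base = exp(1)) {
  p <- if (is(dist, "MarginalDistribution")) dist@probs else as.numeric(dist)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mean occupation fraction of a marginal
#'
#' Expected value of the compartment count divided by the population
#' size; the quantity the deterministic curves trace.
#'
#' @param dist a [MarginalDistribution-class].
#' @param N population size; defaults to the support maximum.
#' @return numeric(1) in `[0, 1]`.
#' @export
expectedFraction <- function(dist, N = max(dist@support)) {
  stopifnot(is(dist, "MarginalDistribution"))
  sum(dist@support * dist@probs) / N
}

#' Probability mass of minor (no-outbreak) final sizes
#'
#' Integrates the steady-state recovered marginal up to an attack-rate
#' bound: `sum of P(R)` over `R <= upperBound`.  With the bound set by
#' the minor-outbreak rule this is the master-equation estimate of the
#' no-outbreak probability.
#'
#' @param dist a [MarginalDistribution-class], normally the recovered
#'   marginal at (near-)steady state.
#' @param upperBound inclusive upper bound on the compartment count
#'   (>= 0; need not be an integer).
#' @return numeric(1), the probability.
#' @seealso [minorOutbreakBound()], [whittleClosedForm()]
#' @export
noOutbreakMass <- function(dist, upperBound) {
  stopifnot(is(dist, "MarginalDistribution"))
  if (upperBound < 0) stop("'upperBound' must be >= 0")
  sum(dist@probs[dist@support <= upperBound])
}

#' Entropy time series of a distribution series
#'
#' Entropy of the infected (or recovered) marginal at each recorded
#' snapshot.
#'
#' @param series a [DistributionSeries-class].
#' @param compartment `"I"` or `"R"`.
#' @param base logarithm base.
#' @return data.frame with columns `time`, `entropy`.
#' @export
entropySeries <- function(series, compartment = c("I", "R"),
                          base = exp(1)) {
  compartment <- match.arg(compartment)
  stopifnot(is(series, "DistributionSeries"))
  sp <- series@space
  marg <- if (sp@model == "SIS") {
    if (compartment != "I") stop("SIS has no recovered compartment")
    series@probs
  } else {
    grp <- if (compartment == "I") sp@labels[, "I"]
           else sp@N - sp@labels[, "S"] - sp@labels[, "I"]
    rowsum(series@probs, group = grp, reorder = TRUE)
  }
  h <- apply(marg, 2L, shannonEntropy, base = base)
  data.frame(time = series@times, entropy = h)
}

#' Order-parameter probability clouds across reproduction numbers
#'
#' For each `R0` on a grid (with `gamma` fixed and `beta = gamma * R0`),
#' propagates an outbreak seeded with `i0` infected and records the
#' distribution of the model's order parameter: the infected marginal of
#' SIS measured in the metastable window at `measureTime`, or the
#' recovered marginal of SIR at the absorbing steady state.  The Shannon
#' entropy of each marginal quantifies the forecast uncertainty of the
#' order parameter.
#'
#' @param model `"SIS"` or `"SIR"`.
#' @param r0Grid numeric vector of reproduction numbers.
#' @param N population size.
#' @param gamma recovery rate (default 0.1).
#' @param i0 initially infected count (default 1).
#' @param measureTime SIS measurement time (default 1000).
#' @param dt propagation step (default 0.1; the SIR steady-state search
#'   uses a coarser internal step, the exponential step being exact for
#'   any `dt`).
#' @param method propagation method, see [propagationConfig()].
#' @return list with `cloud` (data.frame: `r0`, `count`, `fraction`,
#'   `probability`) and `entropy` (data.frame: `r0`, `i0`, `entropy`).
#' @export
orderParameterCloud <- function(model = c("SIS", "SIR"), r0Grid, N,
                                gamma = 0.1, i0 = 1L, measureTime = 1000,
                                dt = 0.1, method = "auto") {
  model <- match.arg(model)
  cloud <- vector("list", length(r0Grid))
  ent <- numeric(length(r0Grid))
  for (k in seq_along(r0Grid)) {
    params <- paramsFromR0(r0Grid[k], N, model, gamma)
    gen <- buildGenerator(params)
    p0 <- if (model == "SIS") deltaState(gen@space, I = i0)
          else deltaState(gen@space, S = N - i0, I = i0)
    marg <- if (model == "SIS") {
      ser <- evolveState(gen, p0, propagationConfig(
        dt = dt, tMax = measureTime, recordStride = round(measureTime / dt),
        method = method))
      marginalInfected(seriesState(ser))
    } else {
      marginalRecovered(steadyStateDistribution(gen, p0, method = method))
    }
    ent[k] <- shannonEntropy(marg)
    cloud[[k]] <- data.frame(r0 = r0Grid[k], count = marg@support,
                             fraction = marg@support / N,
                             probability = marg@probs)
  }
  list(cloud = do.call(rbind, cloud),
       entropy = data.frame(r0 = r0Grid, i0 = as.integer(i0), entropy = ent))
}
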