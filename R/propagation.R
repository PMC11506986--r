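#' Propagation settings
#'
#' @param dt time step of the single-step propagator `exp(H dt)`;
#'   default 0.1 time units.
#' @param tMax propagation horizon (>= dt, or 0 for "initial state only").
#' @param recordStride number of steps between stored snapshots.
#' @param massTolerance allowed deviation of total probability from 1 at
#'   any snapshot; default 1e-9.
#' @param method `"auto"` (dense propagator up to `denseLimit` states,
#'   uniformization above), `"dense"`, or `"uniformization"`.
#' @param denseLimit dimension threshold for the dense path.
#' @return list of validated settings (class `"PropagationConfig"`).
#' @export
propagationConfig <- function(dt = 0.1, tMax = 100, recordStride = 1L,
                              massTolerance = 1e-9,
                              method = c("auto", "dense", "uniformization"),
                              denseLimit = 2000L) {
  method <- match.arg(method)
  stopifnot(dt > 0, tMax >= 0, recordStride >= 1L, massTolerance > 0)
  structure(list(dt = dt, tMax = tMax, recordStride = as.integer(recordStride),
                 massTolerance = massTolerance, method = method,
                 denseLimit = as.integer(denseLimit)),
            class = "PropagationConfig")
}

#' Point-mass (delta) state
#'
#' The probabilistic state with all mass on a single configuration; the
#' usual initial condition of an outbreak seeded by known counts.
#'
#' @param space a [StateSpace-class].
#' @param I infected count of the configuration.
#' @param S susceptible count (SIR only).
#' @param time time stamp; default 0.
#' @return a [ProbabilityVector-class].
#' @examples
#' sp <- buildStateSpace(epidemicParams(0.6, 0.1, 3, "SIS"))
#' deltaState(sp, I = 2)
#' @export
deltaState <- function(space, I, S = NULL, time = 0) {
  stopifnot(is(space, "StateSpace"))
  idx <- if (space@model == "SIS") stateIndex(space, I = I)
         else stateIndex(space, S = S, I = I)
  if (length(idx) != 1L) stop("exactly one configuration label is required")
  p <- numeric(nStates(space))
  p[idx] <- 1
  new("ProbabilityVector", probs = p, time = as.numeric(time), space = space)
}

# Single-step propagator for exp(H * dt).
# Dense path: matrix exponential computed once (Matrix::expm).
# Sparse path: uniformization — with Lambda = max outgoing rate, the jump
# matrix P = I + H/Lambda is column-substochastic and nonnegative, and
# exp(H dt) v = sum_k dpois(k, Lambda dt) P^k v.  The Poisson series is
# truncated where its tail mass drops below truncTol; iterates stay
# nonnegative by construction.
makePropagator <- function(gen, dt, method = "auto", denseLimit = 2000L,
                           truncTol = 1e-13) {
  H <- gen@matrix
  d <- nrow(H)
  if (method == "auto") method <- if (d <= denseLimit) "dense" else
    "uniformization"
  if (method == "dense") {
    U <- as.matrix(Matrix::expm(H * dt))
    list(method = "dense", dt = dt, apply = function(v) drop(U %*% v))
  } else {
    lambda <- max(-Matrix::diag(H))
    if (lambda <= 0) {
      list(method = "uniformization", dt = dt, apply = function(v) v)
    } else {
      P <- H / lambda
      Matrix::diag(P) <- Matrix::diag(P) + 1
      P <- as(P, "CsparseMatrix")
      m <- max(4L, stats::qpois(truncTol, lambda * dt, lower.tail = FALSE) + 2L)
      w <- stats::dpois(0:m, lambda * dt)
      list(method = "uniformization", dt = dt, apply = function(v) {
        out <- w[1L] * v
        term <- v
        for (k in seq_len(m)) {
          term <- as.numeric(P %*% term)
          out <- out + w[k + 1L] * term
        }
        out
      })
    }
  }
}

# Clip tiny negative entries (floating-point debris from the exponential
# action), then renormalize; a genuine mass deficit signals a broken
# generator or too-coarse step and is an error.
cleanProbs <- function(p, massTolerance = 1e-9) {
  neg <- p < 0
  if (any(neg)) {
    if (min(p) < -1e-12)
      stop("propagated state has entries below -1e-12; generator or step ",
           "size is unsound")
    p[neg] <- 0
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-8)
    stop(sprintf("probability mass %.12g deviates from 1 by more than 1e-8",
                 s))
  p / s
}

#' Advance a probabilistic state by one exponential step
#'
#' Applies the propagator `exp(H dt)` to a probability vector.  For
#' repeated stepping use [evolveState()], which computes the propagator
#' once and reuses it.
#'
#' @param gen an [EpidemicGenerator-class].
#' @param p a [ProbabilityVector-class] on the generator's space.
#' @param dt step duration (> 0).
#' @param method see [propagationConfig()].
#' @param massTolerance conservation tolerance.
#' @return the propagated [ProbabilityVector-class] at `p@time + dt`.
#' @examples
#' par <- epidemicParams(0, 0.1, 1, "SIR")
#' g <- buildGenerator(par)
#' p1 <- stepState(g, deltaState(g@space, S = 0, I = 1), dt = 1)
#' p1@probs  # P(I = 1) = exp(-0.1)
#' @export
stepState <- function(gen, p, dt, method = "auto", massTolerance = 1e-9) {
  stopifnot(is(gen, "EpidemicGenerator"), is(p, "ProbabilityVector"), dt > 0)
  if (!identical(dim(p@space@labels), dim(gen@space@labels)) ||
      p@space@model != gen@space@model || p@space@N != gen@space@N)
    stop("probability vector and generator live on different state spaces")
  prop <- makePropagator(gen, dt, method = method)
  q <- cleanProbs(prop$apply(p@probs), massTolerance)
  new("ProbabilityVector", probs = q, time = p@time + dt, space = p@space)
}

#' Evolve the master equation over a time horizon
#'
#' Repeatedly applies the single-step propagator `exp(H dt)` — computed
#' once and reused — recording snapshots every `recordStride` steps.
#' The number of steps is `round(tMax / dt)`, so the final recorded time
#' is within `dt/2` of the requested horizon.
#'
#' @param gen an [EpidemicGenerator-class].
#' @param p0 initial [ProbabilityVector-class].
#' @param config a [propagationConfig()].
#' @return a [DistributionSeries-class] whose first snapshot is `p0`.
#' @examples
#' par <- epidemicParams(0.6, 0.1, 10, "SIS")
#' g <- buildGenerator(par)
#' ser <- evolveState(g, deltaState(g@space, I = 1),
#'                    propagationConfig(dt = 0.1, tMax = 5))
#' @export
evolveState <- function(gen, p0, config = propagationConfig()) {
  stopifnot(is(gen, "EpidemicGenerator"), is(p0, "ProbabilityVector"),
            inherits(config, "PropagationConfig"))
  nSteps <- round(config$tMax / config$dt)
  recordAt <- unique(c(seq(0L, nSteps, by = config$recordStride), nSteps))
  out <- matrix(0, nrow = length(p0@probs), ncol = length(recordAt))
  times <- p0@time + recordAt * config$dt
  out[, 1L] <- p0@probs
  if (nSteps > 0L) {
    prop <- makePropagator(gen, config$dt, method = config$method,
                           denseLimit = config$denseLimit)
    v <- p0@probs
    col <- 2L
    for (s in seq_len(nSteps)) {
      v <- cleanProbs(prop$apply(v), config$massTolerance)
      if (col <= length(recordAt) && s == recordAt[col]) {
        out[, col] <- v
        col <- col + 1L
      }
    }
  }
  new("DistributionSeries", times = times, probs = out, space = p0@space)
}

#' Extract one snapshot of a distribution series
#'
#' @param series a [DistributionSeries-class].
#' @param which snapshot index, or `time =` to select the snapshot
#'   closest to a requested time.
#' @param time optional time; overrides `which`.
#' @return a [ProbabilityVector-class].
#' @export
seriesState <- function(series, which = ncol(series@probs), time = NULL) {
  stopifnot(is(series, "DistributionSeries"))
  if (!is.null(time)) which <- which.min(abs(series@times - time))
  new("ProbabilityVector", probs = series@probs[, which],
      time = series@times[which], space = series@space)
}

#' Propagate to the absorbing steady state
#'
#' Evolves in chunks until the distribution stops changing: the max-norm
#' change of the state per unit time, checked every `checkEvery`
#' recorded chunks, falls below `tol`.  Used for SIR attack-rate clouds
#' and the long-time SIS absorbing state.
#'
#' @param gen an [EpidemicGenerator-class].
#' @param p0 initial [ProbabilityVector-class].
#' @param dt internal step (the exponential step is exact for any `dt`;
#'   a coarser step here only trades Poisson-series length for fewer
#'   steps); default 1.
#' @param checkEvery chunks between convergence checks (each chunk is
#'   10 steps); default 10.
#' @param tol max-norm change per unit time declaring steadiness;
#'   default 1e-8.
#' @param tMax hard cap on the propagation time.
#' @param method see [propagationConfig()].
#' @return a [ProbabilityVector-class] with attributes `converged`
#'   (logical) and `time`.
#' @export
steadyStateDistribution <- function(gen, p0, dt = 1, checkEvery = 10L,
                                    tol = 1e-8, tMax = 1e4,
                                    method = "auto") {
  stopifnot(is(gen, "EpidemicGenerator"), is(p0, "ProbabilityVector"))
  prop <- makePropagator(gen, dt, method = method)
  stepsPerChunk <- 10L
  chunkTime <- stepsPerChunk * dt
  v <- p0@probs
  t <- p0@time
  lastCheck <- v
  converged <- FALSE
  chunk <- 0L
  while (t < tMax) {
    for (s in seq_len(stepsPerChunk)) v <- cleanProbs(prop$apply(v))
    t <- t + chunkTime
    chunk <- chunk + 1L
    if (chunk %% checkEvery == 0L) {
      rate <- max(abs(v - lastCheck)) / (checkEvery * chunkTime)
      if (rate < tol) {
        converged <- TRUE
        break
      }
      lastCheck <- v
    }
  }
  out <- new("ProbabilityVector", probs = v, time = t, space = p0@space)
  attr(out, "converged") <- converged
  out
}

setMethod("show", "ProbabilityVector", function(object) {
  cat(sprintf("ProbabilityVector (%s, N = %d) at t = %g; %d states\n",
              object@space@model, object@space@N, object@time,
              length(object@probs)))
})

setMethod("show", "DistributionSeries", function(object) {
  cat(sprintf(
    "DistributionSeries (%s, N = %d): %d snapshots over t = [%g, %g]\n",
    object@space@model, object@space@N, length(object@times),
    min(object@times), max(object@times)))
})
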