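#' @rdname StateSpace-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname StateSpace-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' Map configuration labels to linear indices
#'
#' Closed-form, bijective map from a configuration label to its position
#' in the frozen state ordering: `I + 1` for SIS, and
#' `(N - S)(N - S + 1)/2 + I + 1` for SIR.
#'
#' @param space a [StateSpace-class].
#' @param ... for SIS, `I =` an integer vector of infected counts; for
#'   SIR, `S =` and `I =` integer vectors (recycled together).
#' @return integer vector of 1-based indices.
#' @examples
#' sp <- buildStateSpace(epidemicParams(0.6, 0.1, 2, "SIR"))
#' stateIndex(sp, S = 1, I = 1)
#' @export
setGeneric("stateIndex", function(space, ...) standardGeneric("stateIndex"))

#' @rdname EpidemicGenerator-class
#' @param x an [EpidemicGenerator-class].
#' @export
setGeneric("generatorMatrix", function(x) standardGeneric("generatorMatrix"))

#' Marginal distribution of the infected compartment
#'
#' Sums the joint probabilities `P(S, I)` over the susceptible count at
#' each fixed `I` (for SIS the state is already the infected marginal
#' and passes through unchanged).
#'
#' @param p a [ProbabilityVector-class].
#' @param ... unused.
#' @return a [MarginalDistribution-class] on support `0:N`.
#' @export
setGeneric("marginalInfected", function(p, ...)
  standardGeneric("marginalInfected"))

#' Marginal distribution of the recovered compartment
#'
#' Sums `P(S, I)` over all configurations with `S + I = N - R` at each
#' fixed recovered count `R`.  Only defined for SIR state spaces.
#'
#' @param p a [ProbabilityVector-class].
#' @param ... unused.
#' @return a [MarginalDistribution-class] on support `0:N`.
#' @export
setGeneric("marginalRecovered", function(p, ...)
  standardGeneric("marginalRecovered"))

#' Locate the infected-fraction peak of a deterministic trajectory
#'
#' Earliest stored grid time attaining the maximum infected fraction.
#' A trajectory whose maximum sits on the boundary of the grid (monotone
#' dynamics, e.g. supercritical SIS rising to its plateau) has no
#' interior peak and is flagged rather than treated as an error.
#'
#' @param traj a [DeterministicTrajectory-class].
#' @param ... unused.
#' @return list with elements `time` (numeric), `height` (numeric) and
#'   `interior` (logical; `FALSE` when the maximum is attained at the
#'   first or last grid point).
#' @export
setGeneric("peakTime", function(traj, ...) standardGeneric("peakTime"))
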