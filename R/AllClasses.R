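#' @import methods
#' @importFrom Matrix sparseMatrix colSums diag drop0 writeMM
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Epidemic model parameters
#'
#' Container for the rates and population size of a compartmental model.
#' Transmission is frequency dependent: a susceptible individual in a
#' well-mixed population of size `N` acquires infection at rate
#' `beta * I / N`, and infectious individuals recover at rate `gamma`.
#' The basic reproduction number is `R0 = beta / gamma`.
#'
#' @slot beta numeric(1), contagion rate per unit time (>= 0).
#' @slot gamma numeric(1), recovery rate per unit time (> 0).
#' @slot N integer(1), closed population size (>= 1).
#' @slot model character(1), `"SIS"` or `"SIR"`.
#'
#' @seealso [epidemicParams()], [basicReproduction()]
#' @export
setClass("EpidemicParams",
  slots = c(beta = "numeric", gamma = "numeric", N = "integer",
            model = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@beta) != 1L || !is.finite(object@beta) ||
        object@beta < 0)
      msgs <- c(msgs, "'beta' must be a single finite number >= 0")
    if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
        object@gamma <= 0)
      msgs <- c(msgs, "'gamma' must be a single finite number > 0")
    if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
      msgs <- c(msgs, "'N' must be a single integer >= 1")
    if (length(object@model) != 1L || !object@model %in% c("SIS", "SIR"))
      msgs <- c(msgs, "'model' must be \"SIS\" or \"SIR\"")
    if (length(msgs)) msgs else TRUE
  })

#' Occupation-number state space of a compartmental model
#'
#' Ordered enumeration of every configuration the stochastic model can
#' occupy.  For SIS the infected count `I` (0..N) labels a configuration
#' (S = N - I is implied); for SIR a pair `(S, I)` with `S + I <= N`
#' labels it (R = N - S - I is implied).  The ordering is frozen:
#' SIS ascending in I; SIR descending in S, then ascending in I, with
#' the closed-form index `(N - S)(N - S + 1)/2 + I + 1`.
#'
#' @slot model character(1), `"SIS"` or `"SIR"`.
#' @slot N integer(1), population size.
#' @slot labels integer matrix, one row per configuration; column `"I"`
#'   (SIS) or columns `"S","I"` (SIR).
#'
#' @seealso [buildStateSpace()], [stateIndex()], [stateLabels()]
#' @export
setClass("StateSpace",
  slots = c(model = "character", N = "integer", labels = "matrix"),
  validity = function(object) {
    n <- object@N
    lab <- object@labels
    if (object@model == "SIS") {
      if (nrow(lab) != n + 1L) return("SIS state space must have N + 1 states")
      if (!identical(colnames(lab), "I")) return("SIS labels need column 'I'")
      if (any(lab[, "I"] < 0L | lab[, "I"] > n))
        return("infected counts must lie in 0..N")
    } else {
      if (nrow(lab) != (n + 1L) * (n + 2L) / 2L)
        return("SIR state space must have (N+1)(N+2)/2 states")
      if (!identical(colnames(lab), c("S", "I")))
        return("SIR labels need columns 'S', 'I'")
      if (any(lab < 0L) || any(rowSums(lab) > n))
        return("labels must satisfy S >= 0, I >= 0, S + I <= N")
    }
    if (anyDuplicated(lab)) return("state labels must be unique")
    TRUE
  })

#' Transition-rate generator of the epidemic master equation
#'
#' Sparse rate matrix `H` over a [StateSpace-class], with the convention
#' `d/dt P = H P` and source configurations as columns: entry `(x', x)`
#' with `x' != x` is the rate of the single-event transition from
#' configuration `x` to `x'`, and each diagonal entry closes its column
#' to zero so that total probability is conserved.  Off-diagonals are
#' nonnegative and columns of absorbing configurations (I = 0) vanish
#' identically.
#'
#' @slot matrix a `dgCMatrix` of transition rates.
#' @slot space the [StateSpace-class] the matrix is indexed by.
#' @slot params the [EpidemicParams-class] the rates were built from.
#'
#' @seealso [buildGenerator()], [generatorMatrix()]
#' @export
setClass("EpidemicGenerator",
  slots = c(matrix = "dgCMatrix", space = "StateSpace",
            params = "EpidemicParams"),
  validity = function(object) {
    H <- object@matrix
    d <- nrow(object@space@labels)
    if (nrow(H) != d || ncol(H) != d)
      return("generator dimension must equal the state-space size")
    offdiag <- H
    Matrix::diag(offdiag) <- 0
    if (any(offdiag@x < 0)) return("off-diagonal rates must be >= 0")
    if (max(abs(Matrix::colSums(H))) > 1e-12)
      return("columns must sum to zero within 1e-12")
    TRUE
  })

#' Probability vector over a state space
#'
#' The coefficients `P(x)` of the probabilistic state, aligned to the
#' frozen ordering of a [StateSpace-class], together with the time the
#' distribution refers to.  Entries are nonnegative and sum to one
#' within 1e-9.
#'
#' @slot probs numeric vector of probabilities, one per configuration.
#' @slot time numeric(1), the time stamp of the distribution.
#' @slot space the [StateSpace-class] the coefficients are aligned to.
#'
#' @seealso [deltaState()], [stepState()], [evolveState()]
#' @export
setClass("ProbabilityVector",
  slots = c(probs = "numeric", time = "numeric", space = "StateSpace"),
  validity = function(object) {
    if (length(object@probs) != nrow(object@space@labels))
      return("probability vector length must match the state space")
    if (any(object@probs < 0)) return("probabilities must be >= 0")
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("probabilities must sum to 1 within 1e-9")
    if (length(object@time) != 1L || !is.finite(object@time))
      return("'time' must be a single finite number")
    TRUE
  })

#' Time series of probability vectors
#'
#' Snapshots of the evolving probabilistic state at strictly increasing
#' times.  Column `j` of `probs` is the distribution at `times[j]`.
#'
#' @slot times numeric vector of strictly increasing snapshot times.
#' @slot probs numeric matrix, one column per snapshot.
#' @slot space the [StateSpace-class] rows are aligned to.
#'
#' @seealso [evolveState()], [seriesState()], [entropySeries()]
#' @export
setClass("DistributionSeries",
  slots = c(times = "numeric", probs = "matrix", space = "StateSpace"),
  validity = function(object) {
    if (ncol(object@probs) != length(object@times))
      return("one probability column per time is required")
    if (nrow(object@probs) != nrow(object@space@labels))
      return("rows must match the state space")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    if (any(object@probs < 0)) return("probabilities must be >= 0")
    if (max(abs(colSums(object@probs) - 1)) > 1e-9)
      return("every snapshot must sum to 1 within 1e-9")
    TRUE
  })

#' Marginal distribution of a single compartment
#'
#' The distribution of one occupation number (infected `I` or recovered
#' `R`) obtained by summing the joint state over all configurations
#' compatible with each value, on the support `0..N`.
#'
#' @slot compartment character(1), `"I"` or `"R"`.
#' @slot support integer vector `0:N`.
#' @slot probs numeric vector of probabilities over the support.
#' @slot time numeric(1), time stamp inherited from the state.
#'
#' @seealso [marginalInfected()], [marginalRecovered()], [shannonEntropy()]
#' @export
setClass("MarginalDistribution",
  slots = c(compartment = "character", support = "integer",
            probs = "numeric", time = "numeric"),
  validity = function(object) {
    if (!object@compartment %in% c("I", "R"))
      return("'compartment' must be \"I\" or \"R\"")
    if (length(object@support) != length(object@probs))
      return("support and probabilities must have equal length")
    if (any(object@probs < 0)) return("probabilities must be >= 0")
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("probabilities must sum to 1 within 1e-9")
    TRUE
  })

#' Deterministic compartmental trajectory
#'
#' Solution of the mean-field ODEs on a stored time grid, as population
#' fractions per compartment (columns `s`, `i` and, for SIR, `r`).
#'
#' @slot model character(1), `"SIS"` or `"SIR"`.
#' @slot times numeric vector of grid times.
#' @slot fractions numeric matrix of compartment fractions, rows match
#'   `times`.
#' @slot params the [EpidemicParams-class] used.
#'
#' @seealso [solveSisOde()], [solveSirOde()], [peakTime()]
#' @export
setClass("DeterministicTrajectory",
  slots = c(model = "character", times = "numeric", fractions = "matrix",
            params = "EpidemicParams"),
  validity = function(object) {
    if (nrow(object@fractions) != length(object@times))
      return("one fraction row per time is required")
    if (any(object@fractions < -1e-9) || any(object@fractions > 1 + 1e-9))
      return("fractions must lie in [0, 1]")
    if (object@model == "SIR" &&
        max(abs(rowSums(object@fractions) - 1)) > 1e-9)
      return("SIR fractions must sum to 1 within 1e-9")
    TRUE
  })

#' Result of the forecast-conditioning experiment
#'
#' Peak-entropy and maximum-entropy-timing statistics per reproduction
#' number and conditioning time, with the per-condition entropy time
#' series optionally retained.
#'
#' @slot summary data.frame with columns `r0`, `dtilde0`, `t0`, `tPeak`,
#'   `peakEntropy`, `tHmax`, `dtildeHmax`, `noPeak`.
#' @slot series list of per-condition data.frames (`time`, `entropy`),
#'   possibly empty.
#' @slot config list of the settings the study was run with.
#'
#' @seealso [runForecastStudy()]
#' @export
setClass("ForecastResult",
  slots = c(summary = "data.frame", series = "list", config = "list"))
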