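#' Construct epidemic parameters
#'
#' @param beta contagion rate per unit time (>= 0).
#' @param gamma recovery rate per unit time (> 0).
#' @param N population size (integer >= 1).
#' @param model `"SIS"` or `"SIR"`.
#' @return an [EpidemicParams-class] object.
#' @examples
#' p <- epidemicParams(beta = 0.6, gamma = 0.1, N = 1000, model = "SIS")
#' basicReproduction(p)
#' @export
epidemicParams <- function(beta, gamma, N, model = c("SIS", "SIR")) {
  model <- match.arg(model)
  new("EpidemicParams", beta = as.numeric(beta), gamma = as.numeric(gamma),
      N = as.integer(N), model = model)
}

#' Basic reproduction number
#'
#' `R0 = beta / gamma`, the mean number of secondary infections caused
#' by one case in a fully susceptible population.
#'
#' @param params an [EpidemicParams-class].
#' @return numeric(1).
#' @export
basicReproduction <- function(params) {
  stopifnot(is(params, "EpidemicParams"))
  params@beta / params@gamma
}

#' Convenience constructor from a reproduction number
#'
#' Fixes `gamma` and sets `beta = gamma * r0`, the parameterisation used
#' when scanning epidemic scenarios over `R0`.
#'
#' @param r0 basic reproduction number (>= 0).
#' @param N population size.
#' @param model `"SIS"` or `"SIR"`.
#' @param gamma recovery rate; default 0.1.
#' @return an [EpidemicParams-class].
#' @export
paramsFromR0 <- function(r0, N, model = c("SIS", "SIR"), gamma = 0.1) {
  epidemicParams(beta = gamma * r0, gamma = gamma, N = N,
                 model = match.arg(model))
}

setMethod("show", "EpidemicParams", function(object) {
  cat(sprintf("EpidemicParams (%s): beta = %g, gamma = %g, N = %d, R0 = %g\n",
              object@model, object@beta, object@gamma, object@N,
              object@beta / object@gamma))
})

#' Enumerate the state space of a compartmental model
#'
#' Builds the complete occupation-number basis of the stochastic model:
#' `N + 1` configurations `I = 0..N` for SIS, and the
#' `(N + 1)(N + 2)/2` pairs `(S, I)` with `S + I <= N` for SIR, ordered
#' by descending `S` and ascending `I` within each `S`.
#'
#' @param params an [EpidemicParams-class].
#' @param maxStates guard on the state-space dimension; SIR spaces grow
#'   quadratically with `N` and the generator memory with the dimension,
#'   so an explicit cap (default 2e5) fails fast instead of exhausting
#'   memory.
#' @return a [StateSpace-class].
#' @examples
#' buildStateSpace(epidemicParams(0.6, 0.1, 3, "SIS"))
#' @export
buildStateSpace <- function(params, maxStates = 2e5) {
  stopifnot(is(params, "EpidemicParams"))
  validObject(params)
  n <- params@N
  if (params@model == "SIS") {
    dim <- n + 1L
    if (dim > maxStates)
      stop("state space has ", dim, " configurations, exceeding maxStates = ",
           maxStates)
    lab <- matrix(0:n, ncol = 1L, dimnames = list(NULL, "I"))
  } else {
    dim <- (n + 1L) * (n + 2L) / 2L
    if (dim > maxStates)
      stop("state space has ", dim, " configurations, exceeding maxStates = ",
           maxStates)
    s <- rep.int(n:0, times = 1L:(n + 1L))
    i <- sequence(1L:(n + 1L)) - 1L
    lab <- cbind(S = s, I = i)
  }
  new("StateSpace", model = params@model, N = n, labels = lab)
}

setMethod("nStates", "StateSpace", function(x) nrow(x@labels))

setMethod("stateLabels", "StateSpace", function(x) x@labels)

setMethod("stateIndex", "StateSpace", function(space, S = NULL, I = NULL) {
  n <- space@N
  if (space@model == "SIS") {
    if (!is.null(S))
      stop("SIS configurations are labelled by I only")
    I <- as.integer(I)
    if (any(I < 0L | I > n)) stop("I out of range 0..N")
    I + 1L
  } else {
    if (is.null(S) || is.null(I))
      stop("SIR configurations need both S and I")
    S <- as.integer(S); I <- as.integer(I)
    if (any(S < 0L | I < 0L | S + I > n))
      stop("labels must satisfy S >= 0, I >= 0, S + I <= N")
    k <- n - S
    (k * (k + 1L)) %/% 2L + I + 1L
  }
})

setMethod("show", "StateSpace", function(object) {
  cat(sprintf("StateSpace (%s, N = %d): %d configurations\n",
              object@model, object@N, nStates(object)))
})

#' Build the master-equation generator
#'
#' Assembles the sparse transition-rate matrix of the epidemic master
#' equation `d/dt P = H P` over a state space.  Each configuration has
#' at most two exits: a contagion event at rate `beta * S * I / N`
#' (SIS: `S = N - I`) taking `I -> I + 1`, and a recovery event at rate
#' `gamma * I` taking `I -> I - 1` (back to susceptible for SIS, into
#' the recovered compartment for SIR).  Source configurations index the
#' columns; the diagonal closes each column to zero so probability is
#' conserved, and every configuration with `I = 0` is absorbing (its
#' column is identically zero).
#'
#' @param params an [EpidemicParams-class].
#' @param space a [StateSpace-class] built from the same parameters;
#'   defaults to `buildStateSpace(params)`.
#' @return an [EpidemicGenerator-class].
#' @examples
#' g <- buildGenerator(epidemicParams(0.6, 0.1, 2, "SIS"))
#' as.matrix(generatorMatrix(g))
#' @export
buildGenerator <- function(params, space = buildStateSpace(params)) {
  stopifnot(is(params, "EpidemicParams"), is(space, "StateSpace"))
  if (space@model != params@model || space@N != params@N)
    stop("state space was built for a different model or population size")
  n <- params@N
  beta <- params@beta
  gamma <- params@gamma
  lab <- space@labels
  if (params@model == "SIS") {
    I <- lab[, "I"]
    S <- n - I
  } else {
    S <- lab[, "S"]
    I <- lab[, "I"]
  }
  from <- seq_len(nrow(lab))
  contRate <- beta * S * I / n
  recRate <- gamma * I
  hasCont <- contRate > 0
  hasRec <- recRate > 0
  if (params@model == "SIS") {
    contTo <- stateIndex(space, I = pmin(I + 1L, n))  # pmin only pads I=N rows
    recTo <- stateIndex(space, I = pmax(I - 1L, 0L))  # dropped by has* masks
  } else {
    contTo <- stateIndex(space, S = pmax(S - 1L, 0L), I = I + (S > 0L))
    recTo <- stateIndex(space, S = S, I = pmax(I - 1L, 0L))
  }
  ii <- c(contTo[hasCont], recTo[hasRec], from)
  jj <- c(from[hasCont], from[hasRec], from)
  xx <- c(contRate[hasCont], recRate[hasRec], -(contRate + recRate))
  keep <- xx != 0
  H <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(nrow(lab), nrow(lab)))
  new("EpidemicGenerator", matrix = as(H, "CsparseMatrix"), space = space,
      params = params)
}

setMethod("generatorMatrix", "EpidemicGenerator", function(x) x@matrix)

setMethod("show", "EpidemicGenerator", function(object) {
  cat(sprintf(
    "EpidemicGenerator (%s, N = %d): %d x %d, %d nonzero rates\n",
    object@params@model, object@params@N, nrow(object@matrix),
    ncol(object@matrix), length(object@matrix@x)))
})
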