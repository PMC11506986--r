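#' Closed-form no-outbreak probability (branching approximation)
#'
#' Under the branching-process (Whittle) approximation with a tree-like
#' assumption for multiple seeds, the probability that an outbreak
#' seeded by `i0` infectious individuals goes extinct before spreading
#' is 1 for `R0 <= 1` and `(1/R0)^i0` for `R0 > 1`; `i0 = 0` always
#' gives 1 (no outbreak can start without seeds).  At `R0 = 1` both
#' branches give 1, so the function is continuous there.
#'
#' @param r0Number basic reproduction number (>= 0).
#' @param i0 initial infectious count (integer >= 0); vectorized.
#' @return numeric vector of probabilities.
#' @examples
#' whittleClosedForm(0.8, 3)  # 1
#' whittleClosedForm(2, 2)    # 0.25
#' @export
whittleClosedForm <- function(r0Number, i0) {
  stopifnot(length(r0Number) == 1L, r0Number >= 0, all(i0 >= 0))
  if (r0Number <= 1) rep(1, length(i0)) else (1 / r0Number)^i0
}

#' Solve the no-outbreak recursion
#'
#' The extinction probability of a lineage satisfies the linear
#' recursion
#' `pi(i) = R0/(R0+1) pi(i+1) + 1/(R0+1) pi(i-1)`
#' with boundary `pi(0) = 1`.  The infinite system is truncated at
#' `iMax` with `pi(iMax) = 0` for `R0 > 1` (large seed counts almost
#' surely ignite) and `pi(iMax) = 1` for `R0 <= 1` (extinction is
#' certain); the truncation error against the closed form decays as
#' `R0^-iMax`.
#'
#' @param r0Number basic reproduction number (> 0).
#' @param iMax truncation level (integer >= 2); default 200.
#' @return numeric vector `pi(0..iMax)` named by seed count.
#' @examples
#' solveWhittleRecursion(2, iMax = 40)[["1"]]  # 0.5
#' @export
solveWhittleRecursion <- function(r0Number, iMax = 200L) {
  stopifnot(r0Number > 0, iMax >= 2L)
  iMax <- as.integer(iMax)
  up <- r0Number / (r0Number + 1)
  down <- 1 / (r0Number + 1)
  piTop <- if (r0Number > 1) 0 else 1
  m <- iMax - 1L
  # interior equations: -down*pi(i-1) + pi(i) - up*pi(i+1) = 0
  A <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L),
                          diagonals = list(rep(-down, m - 1L), rep(1, m),
                                           rep(-up, m - 1L)))
  rhs <- numeric(m)
  rhs[1L] <- down * 1
  rhs[m] <- rhs[m] + up * piTop
  sol <- as.numeric(Matrix::solve(A, rhs))
  stats::setNames(c(1, sol, piTop), 0:iMax)
}

#' Consistency of the full-rate recursion with the generator
#'
#' With `S0` susceptibles and `I0` infectious the competing events are
#' contagion at rate `beta S0 I0 / N` and recovery at rate `gamma I0`,
#' exactly the generator matrix elements for the transitions
#' `(S0, I0) -> (S0-1, I0+1)` and `(S0, I0) -> (S0, I0-1)`.  This check
#' recomputes both rates from the assembled generator, forms the branch
#' weights of the first-step decomposition, and reports the reduced
#' weights `(R0/(R0+1), 1/(R0+1))` obtained when `S0 = N`.
#'
#' @param params an [EpidemicParams-class] (model `"SIR"`).
#' @param s0 susceptible count.
#' @param i0 infectious count (>= 1).
#' @return list with `contagionRate`, `recoveryRate`,
#'   `generatorContagion`, `generatorRecovery`, `weights` (contagion,
#'   recovery), `reducedWeights`, and `ratesMatch` (logical).
#' @export
whittleRateCheck <- function(params, s0, i0) {
  stopifnot(is(params, "EpidemicParams"), params@model == "SIR",
            s0 >= 1, i0 >= 1)
  n <- params@N
  contagion <- params@beta * s0 * i0 / n
  recovery <- params@gamma * i0
  if (s0 + i0 <= n) {
    gen <- buildGenerator(params)
    H <- gen@matrix
    from <- stateIndex(gen@space, S = s0, I = i0)
    genCont <- H[stateIndex(gen@space, S = s0 - 1L, I = i0 + 1L), from]
    genRec <- H[stateIndex(gen@space, S = s0, I = i0 - 1L), from]
  } else {
    # S0 = N with seeds on top is the branching-limit idealisation; it is
    # not a basis configuration, so there are no generator entries to match
    genCont <- NA_real_
    genRec <- NA_real_
  }
  total <- contagion + recovery
  r0 <- basicReproduction(params)
  list(contagionRate = contagion, recoveryRate = recovery,
       generatorContagion = genCont, generatorRecovery = genRec,
       weights = c(contagion = contagion / total,
                   recovery = recovery / total),
       reducedWeights = c(contagion = r0 / (r0 + 1),
                          recovery = 1 / (r0 + 1)),
       ratesMatch = if (is.na(genCont)) NA else
         isTRUE(all.equal(c(contagion, recovery), c(genCont, genRec),
                          tolerance = 1e-12)))
}

#' Minor-outbreak attack-rate bound
#'
#' The attack-rate threshold below which an SIR trajectory counts as a
#' minor outbreak: `fraction * R_det + i0` when `R0 > 1` (with `R_det`
#' the deterministic major-outbreak attack rate in individuals) and
#' `fraction * N + i0` when `R0 <= 1`, where no major outbreak exists.
#'
#' @param params an [EpidemicParams-class].
#' @param i0 seed count.
#' @param fraction threshold multiplier in (0, 1); default 0.2.
#' @param deterministicAttack optional attack-rate count for `R0 > 1`;
#'   computed from [sirFinalSize()] with `s0 = (N - i0)/N` when missing.
#' @return numeric(1), the bound in individuals.
#' @export
minorOutbreakBound <- function(params, i0, fraction = 0.2,
                               deterministicAttack = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  n <- params@N
  if (basicReproduction(params) > 1) {
    if (is.null(deterministicAttack))
      deterministicAttack <- n * sirFinalSize(basicReproduction(params),
                                              s0 = (n - i0) / n, r0Init = 0)
    fraction * deterministicAttack + i0
  } else {
    fraction * n + i0
  }
}
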