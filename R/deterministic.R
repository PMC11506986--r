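#' Closed-form deterministic SIS trajectory
#'
#' The mean-field SIS infected fraction obeys the logistic law
#' `d rho/dt = (beta - gamma) rho - beta rho^2`, solved here in closed
#' form (with the degenerate cases `beta = 0`, pure exponential decay,
#' and `beta = gamma` handled separately).  For `R0 > 1` the trajectory
#' approaches the endemic plateau `1 - 1/R0`.
#'
#' @param params an [EpidemicParams-class] (model `"SIS"`).
#' @param rho0 initial infected fraction in `[0, 1]`.
#' @param tGrid numeric vector of times (default a 0.01-step grid to
#'   t = 100).
#' @return a [DeterministicTrajectory-class] with columns `s`, `i`.
#' @examples
#' tr <- solveSisOde(epidemicParams(0.6, 0.1, 1000, "SIS"), 0.001,
#'                   seq(0, 50, by = 0.1))
#' tail(tr@fractions[, "i"], 1)  # ~ 1 - 1/6
#' @export
solveSisOde <- function(params, rho0, tGrid = seq(0, 100, by = 0.01)) {
  stopifnot(is(params, "EpidemicParams"), rho0 >= 0, rho0 <= 1)
  beta <- params@beta
  gamma <- params@gamma
  r <- beta - gamma
  t <- tGrid - tGrid[1L]
  rho <-
    if (beta == 0) {
      rho0 * exp(-gamma * t)
    } else if (r == 0) {
      rho0 / (1 + beta * rho0 * t)
    } else {
      # r*rho0 / (r e^{-rt} + beta rho0 (1 - e^{-rt})): overflow-safe for r>0
      e <- exp(-r * t)
      r * rho0 / (r * e + beta * rho0 * (1 - e))
    }
  rho <- pmin(pmax(rho, 0), 1)
  frac <- cbind(s = 1 - rho, i = rho)
  new("DeterministicTrajectory", model = "SIS", times = tGrid,
      fractions = frac, params = params)
}

sirRhs <- function(t, y, parms) {
  inc <- parms$beta * y[1L] * y[2L]
  list(c(-inc, inc - parms$gamma * y[2L], parms$gamma * y[2L]))
}

#' Deterministic SIR trajectory
#'
#' Integrates `ds/dt = -beta s i`, `di/dt = beta s i - gamma i`,
#' `dr/dt = gamma i` (fractions of the population) with an adaptive
#' high-accuracy solver (relative tolerance 1e-10).
#'
#' @param params an [EpidemicParams-class] (model `"SIR"`).
#' @param s0,i0,r0 initial fractions summing to 1 within 1e-12.
#' @param tGrid numeric vector of times.
#' @return a [DeterministicTrajectory-class] with columns `s`, `i`, `r`.
#' @export
solveSirOde <- function(params, s0, i0, r0 = 1 - s0 - i0,
                        tGrid = seq(0, 100, by = 0.01)) {
  stopifnot(is(params, "EpidemicParams"))
  if (abs(s0 + i0 + r0 - 1) > 1e-12)
    stop("initial fractions must sum to 1 within 1e-12")
  sol <- deSolve::ode(y = c(s = s0, i = i0, r = r0), times = tGrid,
                      func = sirRhs,
                      parms = list(beta = params@beta, gamma = params@gamma),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0)
    stop("SIR integration failed to meet its tolerance")
  frac <- unname(sol[, c("s", "i", "r"), drop = FALSE])
  colnames(frac) <- c("s", "i", "r")
  frac <- pmin(pmax(frac, 0), 1)
  frac <- frac / rowSums(frac)
  new("DeterministicTrajectory", model = "SIR", times = as.numeric(sol[, 1L]),
      fractions = frac, params = params)
}

#' Final size of a deterministic SIR outbreak
#'
#' Solves the implicit attack-rate relation
#' `rho = 1 - s0 * exp(-R0 * rho) - r0` for the largest root in
#' `[0, 1]` by bracketing and bisection to 1e-12.  When no positive root
#' exists in the bracket (subcritical outbreaks with vanishing seed) the
#' attack rate 0 is returned.
#'
#' @param r0Number basic reproduction number.
#' @param s0 initial susceptible fraction (default 1).
#' @param r0Init initial recovered fraction (default 0).
#' @return the attack rate, a fraction in `[0, 1]`.
#' @examples
#' sirFinalSize(2)          # ~ 0.7968
#' sirFinalSize(0.8)        # 0: subcritical
#' @export
sirFinalSize <- function(r0Number, s0 = 1, r0Init = 0) {
  stopifnot(r0Number >= 0, s0 >= 0, s0 <= 1, r0Init >= 0, r0Init <= 1,
            s0 + r0Init <= 1 + 1e-12)
  f <- function(rho) 1 - s0 * exp(-r0Number * rho) - r0Init - rho
  lo <- 1e-9
  hi <- 1
  # f(hi) <= 0 always; a positive root exists iff f(lo) > 0 (either a
  # nonzero seed i0 = 1 - s0 - r0Init, or s0 * R0 > 1)
  if (f(lo) <= 0) return(0)
  if (f(hi) >= 0) return(1)
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

setMethod("peakTime", "DeterministicTrajectory", function(traj, ...) {
  i <- traj@fractions[, "i"]
  idx <- which.max(i)
  interior <- idx > 1L && idx < length(i) &&
    i[idx] > i[1L] && i[idx] > i[length(i)]
  list(time = traj@times[idx], height = i[idx], interior = interior)
})

setMethod("show", "DeterministicTrajectory", function(object) {
  pk <- peakTime(object)
  cat(sprintf(
    "DeterministicTrajectory (%s): %d grid points over t = [%g, %g]; %s\n",
    object@model, length(object@times), min(object@times), max(object@times),
    if (pk$interior) sprintf("peak i = %.4g at t = %.4g", pk$height, pk$time)
    else "no interior peak"))
})
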