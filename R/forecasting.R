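#' Forecast-conditioning study settings
#'
#' The study conditions the probabilistic state on points of a
#' deterministic reference trajectory and measures how the uncertainty
#' of the epidemic peak depends on the conditioning time, expressed as
#' the relative offset `dtilde0 = (t0 - tPeak)/tPeak` in `[-1, 0]`.
#'
#' @param r0List reproduction numbers of the reference outbreaks;
#'   default `c(2, 4, 6)`.
#' @param N population size (default 100, >= 10).
#' @param gamma recovery rate (default 0.1; `beta = gamma * R0`).
#' @param i0 seed count of the reference trajectory (default 1).
#' @param dt propagation step (default 0.1).
#' @param relTimes grid of relative conditioning offsets in `[-1, 0]`;
#'   default 21 equally spaced points.
#' @param horizonFactor propagation horizon as a multiple of the peak
#'   time (default 2).
#' @return validated settings list (class `"ForecastConfig"`).
#' @export
forecastConfig <- function(r0List = c(2, 4, 6), N = 100L, gamma = 0.1,
                           i0 = 1L, dt = 0.1,
                           relTimes = seq(-1, 0, length.out = 21L),
                           horizonFactor = 2) {
  stopifnot(N >= 10L, all(relTimes >= -1), all(relTimes <= 0), dt > 0,
            horizonFactor > 1)
  structure(list(r0List = r0List, N = as.integer(N), gamma = gamma,
                 i0 = as.integer(i0), dt = dt, relTimes = relTimes,
                 horizonFactor = horizonFactor),
            class = "ForecastConfig")
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Condition the probabilistic state on a trajectory point
#'
#' Reads the deterministic fractions `(s(t0), i(t0))`, maps them to
#' integer counts by nearest-integer rounding of `s N` and `i N`
#' (repairing `S + I > N` by decrementing `S`, then `I`), and returns
#' the point-mass state at that configuration — the analogue of a
#' measurement collapsing the ensemble onto observed data.
#'
#' @param traj a [DeterministicTrajectory-class] (model `"SIR"`).
#' @param t0 conditioning time within the trajectory span.
#' @param space the SIR [StateSpace-class] to condition on.
#' @return a [ProbabilityVector-class] with mass 1 at one configuration
#'   and time stamp `t0`.
#' @export
conditionOnTrajectory <- function(traj, t0, space) {
  stopifnot(is(traj, "DeterministicTrajectory"), traj@model == "SIR",
            is(space, "StateSpace"), space@model == "SIR")
  if (t0 < min(traj@times) || t0 > max(traj@times))
    stop("'t0' lies outside the trajectory span")
  n <- space@N
  s <- stats::approx(traj@times, traj@fractions[, "s"], xout = t0)$y
  i <- stats::approx(traj@times, traj@fractions[, "i"], xout = t0)$y
  S <- roundHalfUp(s * n)
  I <- roundHalfUp(i * n)
  while (S + I > n && S > 0L) S <- S - 1L
  while (S + I > n && I > 0L) I <- I - 1L
  deltaState(space, S = S, I = I, time = t0)
}

#' Relative conditioning and maximum-entropy offsets
#'
#' `dtilde0 = (t0 - tPeak)/tPeak` locates the conditioning time
#' relative to the epidemic peak (`-1` at outbreak start, `0` at the
#' peak); `dtildeHmax = (tHmax - tPeak)/tPeak` locates the time of
#' maximal forecast entropy the same way.
#'
#' @param t0 conditioning time.
#' @param tPeak deterministic peak time (> 0).
#' @param tHmax time of maximal entropy.
#' @return list with `dtilde0` and `dtildeHmax`.
#' @export
relativeTimes <- function(t0, tPeak, tHmax) {
  if (tPeak <= 0) stop("'tPeak' must be > 0")
  list(dtilde0 = (t0 - tPeak) / tPeak, dtildeHmax = (tHmax - tPeak) / tPeak)
}

#' Entropy of the infected marginal at the reference peak
#'
#' Conditions the state on the trajectory at `t0`, propagates it to the
#' deterministic peak time, and returns the Shannon entropy of the
#' infected marginal there.  Conditioning exactly at the peak gives 0
#' (a point mass needs no propagation).
#'
#' @param gen the SIR [EpidemicGenerator-class].
#' @param traj the reference [DeterministicTrajectory-class].
#' @param t0 conditioning time (<= peak time).
#' @param dt propagation step; default 0.1.
#' @return numeric(1), the entropy in nats.
#' @export
peakEntropy <- function(gen, traj, t0, dt = 0.1) {
  pk <- peakTime(traj)
  if (t0 > pk$time) stop("'t0' must not exceed the peak time")
  p0 <- conditionOnTrajectory(traj, t0, gen@space)
  if (pk$time - t0 < dt / 2) return(0)
  ser <- evolveState(gen, p0, propagationConfig(
    dt = dt, tMax = pk$time - t0,
    recordStride = max(1L, round((pk$time - t0) / dt))))
  shannonEntropy(marginalInfected(seriesState(ser)))
}

#' Run the forecast-conditioning study
#'
#' For each reproduction number, builds the deterministic SIR reference
#' trajectory seeded with `i0` individuals, conditions the
#' master-equation state on the trajectory at each relative offset
#' `dtilde0`, propagates over `[t0, horizonFactor * tPeak]`, and
#' records the entropy of the infected marginal over time.  Reported
#' per condition: the entropy at the deterministic peak
#' (`peakEntropy`), the time of maximal entropy in the window
#' (earliest-argmax tie-break) and its relative offset `dtildeHmax`.
#' Scenarios with `R0 <= 1` have no deterministic peak and are flagged
#' (`noPeak`) rather than evaluated.
#'
#' @param config a [forecastConfig()].
#' @param keepSeries retain the per-condition entropy time series;
#'   default `TRUE`.
#' @return a [ForecastResult-class].
#' @export
runForecastStudy <- function(config = forecastConfig(), keepSeries = TRUE) {
  stopifnot(inherits(config, "ForecastConfig"))
  rows <- list()
  series <- list()
  for (r0 in config$r0List) {
    params <- paramsFromR0(r0, config$N, "SIR", config$gamma)
    i0frac <- config$i0 / config$N
    grid <- seq(0, 60 / config$gamma, by = 0.01)
    traj <- solveSirOde(params, s0 = 1 - i0frac, i0 = i0frac, r0 = 0,
                        tGrid = grid)
    pk <- peakTime(traj)
    if (r0 <= 1 || !pk$interior) {
      rows[[length(rows) + 1L]] <- data.frame(
        r0 = r0, dtilde0 = config$relTimes, t0 = NA_real_, tPeak = NA_real_,
        peakEntropy = NA_real_, tHmax = NA_real_, dtildeHmax = NA_real_,
        noPeak = TRUE)
      next
    }
    gen <- buildGenerator(params)
    for (rel in config$relTimes) {
      t0 <- pk$time * (1 + rel)
      p0 <- conditionOnTrajectory(traj, t0, gen@space)
      horizon <- config$horizonFactor * pk$time - t0
      ser <- evolveState(gen, p0, propagationConfig(
        dt = config$dt, tMax = max(horizon, config$dt)))
      ent <- entropySeries(ser, "I")
      hPeak <- ent$entropy[which.min(abs(ent$time - pk$time))]
      if (abs(t0 - pk$time) < config$dt / 2) hPeak <- ent$entropy[1L]
      iMax <- which.max(ent$entropy)  # which.max takes the earliest argmax
      tHmax <- ent$time[iMax]
      relT <- relativeTimes(t0, pk$time, tHmax)
      rows[[length(rows) + 1L]] <- data.frame(
        r0 = r0, dtilde0 = rel, t0 = t0, tPeak = pk$time,
        peakEntropy = hPeak, tHmax = tHmax, dtildeHmax = relT$dtildeHmax,
        noPeak = FALSE)
      if (keepSeries)
        series[[sprintf("r0=%g,dtilde0=%g", r0, rel)]] <- ent
    }
  }
  new("ForecastResult", summary = do.call(rbind, rows), series = series,
      config = unclass(config))
}

setMethod("show", "ForecastResult", function(object) {
  cat(sprintf(
    "ForecastResult: %d conditions over R0 in {%s}\n",
    nrow(object@summary),
    paste(unique(object@summary$r0), collapse = ", ")))
})
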