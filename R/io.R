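fmt17 <- function(x) sprintf("%.17g", x)

#' Export a state-space label table
#'
#' CSV with columns `index`, `S`, `I`, `R` in the frozen state ordering
#' (for SIS, `S = N - I` and `R = 0`).
#'
#' @param space a [StateSpace-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeStateSpaceCSV <- function(space, file) {
  stopifnot(is(space, "StateSpace"))
  lab <- space@labels
  if (space@model == "SIS") {
    tab <- data.frame(index = seq_len(nrow(lab)), S = space@N - lab[, "I"],
                      I = lab[, "I"], R = 0L)
  } else {
    tab <- data.frame(index = seq_len(nrow(lab)), S = lab[, "S"],
                      I = lab[, "I"],
                      R = space@N - lab[, "S"] - lab[, "I"])
  }
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a generator in Matrix Market format
#'
#' @param gen an [EpidemicGenerator-class].
#' @param file output path (`.mtx`).
#' @return the path, invisibly.
#' @export
writeGeneratorMTX <- function(gen, file) {
  stopifnot(is(gen, "EpidemicGenerator"))
  Matrix::writeMM(gen@matrix, file)
  invisible(file)
}

#' Export a distribution series as long-format CSV
#'
#' One row per (time, configuration): `time`, `index`, the label
#' columns (`S`, `I`, `R`), the occupation fraction of the infected
#' compartment (`rho_i`) and the probability, at full double precision.
#'
#' @param series a [DistributionSeries-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeDistributionSeriesCSV <- function(series, file) {
  stopifnot(is(series, "DistributionSeries"))
  sp <- series@space
  lab <- sp@labels
  nT <- length(series@times)
  nS <- nrow(lab)
  if (sp@model == "SIS") {
    S <- sp@N - lab[, "I"]; I <- lab[, "I"]; R <- rep.int(0L, nS)
  } else {
    S <- lab[, "S"]; I <- lab[, "I"]; R <- sp@N - S - I
  }
  tab <- data.frame(
    time = fmt17(rep(series@times, each = nS)),
    index = rep.int(seq_len(nS), nT),
    S = rep.int(S, nT), I = rep.int(I, nT), R = rep.int(R, nT),
    rho_i = fmt17(rep.int(I, nT) / sp@N),
    probability = fmt17(as.numeric(series@probs)))
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a compact JSON summary of a distribution series
#'
#' Per snapshot: time, mean and variance of the infected count, and the
#' Shannon entropy of the infected marginal (nats).
#'
#' @param series a [DistributionSeries-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSeriesSummaryJSON <- function(series, file) {
  stopifnot(is(series, "DistributionSeries"))
  sp <- series@space
  iCount <- if (sp@model == "SIS") sp@labels[, "I"] else sp@labels[, "I"]
  m <- as.numeric(crossprod(series@probs, iCount))
  m2 <- as.numeric(crossprod(series@probs, iCount^2))
  ent <- entropySeries(series, "I")$entropy
  out <- data.frame(time = series@times, mean = m, variance = m2 - m^2,
                    entropy = ent)
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Generate the analytic reference fixtures
#'
#' Writes the small closed-form reference systems used for validation:
#' the N = 1 pure-death chain (survival table `exp(-gamma t)`), the
#' N = 2 transmission-free SIR whose infected marginal is binomial with
#' success probability `exp(-gamma t)`, and the enumerated
#' single-event transition tables for SIS and SIR at N = 6, against
#' which the assembled generators can be compared entry by entry.  A
#' manifest records every file with its provenance.
#'
#' @param dir output directory (created if missing).
#' @param gamma recovery rate of the reference chains; default 0.1.
#' @return invisible character vector of the files written.
#' @export
generateFixtures <- function(dir, gamma = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  tGrid <- seq(0, 20, by = 1)
  pure <- data.frame(time = tGrid, p_infected = fmt17(exp(-gamma * tGrid)))
  f <- file.path(dir, "pure_death_N1.csv")
  utils::write.csv(pure, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  pSurv <- exp(-gamma * tGrid)
  binom <- data.frame(time = rep(tGrid, each = 3L),
                      I = rep.int(0:2, length(tGrid)),
                      probability = fmt17(as.numeric(vapply(
                        pSurv, function(p) stats::dbinom(0:2, 2L, p),
                        numeric(3L)))))
  f <- file.path(dir, "binomial_recovery_N2.csv")
  utils::write.csv(binom, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  for (model in c("SIS", "SIR")) {
    params <- epidemicParams(0.6, gamma, 6L, model)
    tab <- enumerateTransitions(params)
    tab$rate <- fmt17(tab$rate)
    f <- file.path(dir, sprintf("transitions_%s_N6.csv", model))
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    files = data.frame(
      file = basename(files),
      provenance = c(
        "closed form exp(-gamma t) for the N=1 single-recovery chain",
        "binomial(2, exp(-gamma t)) infected marginal of the beta=0 N=2 SIR",
        "all single-event transitions of the SIS model at N=6, beta=0.6",
        "all single-event transitions of the SIR model at N=6, beta=0.6")),
    gamma = gamma)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, digits = NA, auto_unbox = TRUE)
  invisible(c(files, mf))
}

#' Enumerate all single-event transitions from the model rules
#'
#' Direct enumeration of the allowed contagion and recovery events from
#' the verbal model definition, independent of the generator assembly:
#' for every configuration, a contagion event (rate `beta S I / N`)
#' and a recovery event (rate `gamma I`) where allowed.
#'
#' @param params an [EpidemicParams-class].
#' @return data.frame with columns `from_S`, `from_I`, `to_S`, `to_I`,
#'   `event`, `rate`.
#' @export
enumerateTransitions <- function(params) {
  n <- params@N
  rows <- list()
  addRow <- function(fs, fi, ts, ti, event, rate) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from_S = fs, from_I = fi, to_S = ts, to_I = ti, event = event,
      rate = rate)
  }
  if (params@model == "SIS") {
    for (I in 0:n) {
      S <- n - I
      if (S >= 1L && I >= 1L)
        addRow(S, I, S - 1L, I + 1L, "contagion", params@beta * S * I / n)
      if (I >= 1L)
        addRow(S, I, S + 1L, I - 1L, "recovery", params@gamma * I)
    }
  } else {
    for (S in n:0) for (I in 0:(n - S)) {
      if (S >= 1L && I >= 1L)
        addRow(S, I, S - 1L, I + 1L, "contagion", params@beta * S * I / n)
      if (I >= 1L)
        addRow(S, I, S, I - 1L, "recovery", params@gamma * I)
    }
  }
  do.call(rbind, rows)
}
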