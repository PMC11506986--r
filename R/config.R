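runConfigDefaults <- list(
  subcommand = NULL,
  params = list(beta = NULL, gamma = NULL, N = NULL, model = "SIS"),
  propagation = list(dt = 0.1, tMax = 100, recordStride = 1L),
  experiment = list(i0 = 1L, r0Grid = NULL, tau = 0.05, nRuns = 1000L,
                    fraction = 0.2, relTimes = NULL, horizonFactor = 2),
  outDir = ".",
  seed = 1L,
  logLevel = "info")

checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key%s in %s: %s",
                 if (length(unknown) > 1L) "s" else "", where,
                 paste(unknown, collapse = ", ")))
}

#' Read and validate a run configuration
#'
#' Loads a YAML (or JSON) configuration, fills defaults, rejects
#' unknown keys with a field-level message, and validates the parameter
#' block.  Explicit `overrides` (e.g. from command-line flags) take
#' precedence over file values.
#'
#' @param path path to a YAML or JSON configuration file, or `NULL` to
#'   start from defaults.
#' @param overrides named list merged over the file values (nested
#'   lists merge by key).
#' @return validated configuration list (class `"RunConfig"`).
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- runConfigDefaults
  fromFile <- if (is.null(path)) list()
    else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  mergeBlocks <- function(base, extra, where) {
    checkKeys(extra, names(base), where)
    for (k in names(extra)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(extra[[k]]))
        mergeBlocks(base[[k]], extra[[k]], paste0(where, "$", k))
      else extra[[k]]
    }
    base
  }
  cfg <- mergeBlocks(cfg, fromFile, "config")
  cfg <- mergeBlocks(cfg, overrides, "overrides")
  p <- cfg$params
  if (!is.null(p$beta) && p$beta < 0)
    stop("params$beta must be >= 0")
  if (!is.null(p$gamma) && p$gamma <= 0)
    stop("params$gamma must be > 0")
  if (!is.null(p$N) && p$N < 1)
    stop("params$N must be >= 1")
  if (!is.null(p$model) && !p$model %in% c("SIS", "SIR"))
    stop("params$model must be \"SIS\" or \"SIR\"")
  if (cfg$propagation$dt <= 0) stop("propagation$dt must be > 0")
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly through [readRunConfig()].
#'
#' @param config a `"RunConfig"` list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  drop <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop)
      x[!vapply(x, is.null, logical(1L))]
    } else x
  }
  yaml::write_yaml(drop(unclass(config)), path)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' JSON manifest recording the configuration hash, seed, package
#' version and output files of a run; deliberately free of timestamps
#' so deterministic runs stay byte-reproducible.
#'
#' @param dir output directory.
#' @param config a `"RunConfig"` list.
#' @param files character vector of files the run wrote.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, config, files = character()) {
  cfgFile <- tempfile(fileext = ".yml")
  on.exit(unlink(cfgFile))
  writeRunConfig(config, cfgFile)
  manifest <- list(
    configHash = unname(tools::md5sum(cfgFile)),
    seed = config$seed,
    package = "epiMaster",
    version = as.character(utils::packageVersion("epiMaster")),
    files = basename(files))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
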