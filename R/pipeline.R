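## End-to-end orchestration: synthetic data (or CSV input) -> survival
## spectra -> classification -> diffusion fractions -> three-state search
## model -> energy landscape -> optional cell context, as one reportable
## unit per variant.

#' Pipeline configuration with field-standard defaults
#'
#' All analysis constants are surfaced here and nowhere hard-coded in
#' stage code: classification threshold 0.01 1/s, closure ratio
#' koffS/kd = 0.0705, 500 spectrum and 400 diffusion resamples, a
#' 200-point log-spaced rate grid on [1e-4, 20] 1/s.
#'
#' @param name variant label
#' @param preset `"wt"` to simulate from [wtPreset()], or `NULL` when
#'   file inputs are given
#' @param survivalPath,tracksPath optional CSV inputs replacing simulation
#' @param nEvents simulated binding events per condition
#' @param nTracks simulated fast-tracking tracks
#' @param threshold specific/unspecific classification threshold (1/s)
#' @param ratio closure ratio koffS/kd
#' @param rateGridSpec `c(kMin, kMax, nPoints)` for the rate grid
#' @param nSpectrumResamples,nDiffusionResamples resample counts (0
#'   disables resampling)
#' @param resampleFraction fraction of data per resample
#' @param nSites,moleculeCount,volumeUm3 optional cell-context inputs
#' @param seed integer master seed
#' @return configuration list (class `"pipelineConfig"`)
#' @export
pipelineConfig <- function(name = "WT", preset = "wt",
                           survivalPath = NULL, tracksPath = NULL,
                           nEvents = 40000L, nTracks = 4500L,
                           threshold = 0.01, ratio = 0.0705,
                           rateGridSpec = c(1e-4, 20, 200),
                           nSpectrumResamples = 500L,
                           nDiffusionResamples = 400L,
                           resampleFraction = 0.8,
                           nSites = NULL, moleculeCount = NULL,
                           volumeUm3 = NULL, seed = 1L) {
  cfg <- list(name = name, preset = preset, survivalPath = survivalPath,
              tracksPath = tracksPath, nEvents = as.integer(nEvents),
              nTracks = as.integer(nTracks), threshold = threshold,
              ratio = ratio, rateGridSpec = rateGridSpec,
              nSpectrumResamples = as.integer(nSpectrumResamples),
              nDiffusionResamples = as.integer(nDiffusionResamples),
              resampleFraction = resampleFraction, nSites = nSites,
              moleculeCount = moleculeCount, volumeUm3 = volumeUm3,
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipelineConfig()]. The configuration round-trips through
#' serialization unchanged.
#'
#' @param path YAML or JSON file
#' @return configuration list as from [pipelineConfig()]
#' @export
readPipelineConfig <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
    simplifyVector = TRUE) else yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, x)
}

#' Run the full inference pipeline for one variant
#'
#' Simulates (or reads) survival and fast-tracking data, infers the
#' dissociation-rate spectrum, classifies it at the configured threshold,
#' fits the jump-distance mixture for the bound fraction, splits the
#' fractions, solves the three-state search model under the configured
#' closure and assembles the energy landscape and optional cell context.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()]
#' @param conditions time-lapse conditions (default [standardConditions()])
#' @param verbose print per-stage progress
#' @return a [VariantReport-class]
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(nEvents = 5000, nTracks = 2000,
#'                       nSpectrumResamples = 0, nDiffusionResamples = 0)
#' rep <- runPipeline(cfg)
#' residenceTimes(rep@classes)
#' }
#' @export
runPipeline <- function(config, conditions = standardConditions(),
                        verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  note <- function(...) if (verbose) message(...)
  seed <- config$seed

  # --- input stage -----------------------------------------------------
  if (!is.null(config$survivalPath)) {
    if (!file.exists(config$survivalPath))
      stop("survival input not found: ", config$survivalPath)
    durations <- readSurvivalData(config$survivalPath)
    conditions <- conditions[match(names(durations), names(conditions))]
  } else if (identical(config$preset, "wt")) {
    preset <- wtPreset(nTracks = config$nTracks, seed = seed)
    durations <- simulateSurvivalData(preset$spectrum, conditions,
                                      nEvents = config$nEvents,
                                      seed = seed, count = "observed")
  } else stop("no input: give a preset name or a survivalPath")
  note("survival events per condition: ",
       paste(lengths(durations), collapse = ", "))

  # --- spectrum --------------------------------------------------------
  hists <- lapply(seq_along(durations), function(i)
    buildSurvivalHistogram(durations[[i]], conditions[[i]]))
  spectrum <- inferSpectrum(hists, rateGridSpec = config$rateGridSpec)
  note("bleach number: ", signif(spectrum@bleachNumber, 3))
  resamples <- NULL
  if (config$nSpectrumResamples > 0)
    resamples <- resampleSpectra(durations, conditions,
                                 nResamples = config$nSpectrumResamples,
                                 fraction = config$resampleFraction,
                                 seed = seed,
                                 rateGridSpec = config$rateGridSpec)
  classes <- classifySpectrum(spectrum, config$threshold, resamples)
  note("tau_s = ", signif(classes@tauS, 4), " s, tau_u = ",
       signif(classes@tauU, 4), " s")

  # --- diffusion -------------------------------------------------------
  if (!is.null(config$tracksPath)) {
    if (!file.exists(config$tracksPath))
      stop("track input not found: ", config$tracksPath)
    tracks <- readTrackTable(config$tracksPath, frameInterval = 0.0117)
  } else {
    tracks <- simulateJumpData(preset$diffusion)
  }
  jumps <- collectJumps(tracks)
  diffFit <- if (config$nDiffusionResamples > 0)
    resampleFit(jumps, nComponents = 3L,
                nResamples = config$nDiffusionResamples,
                fraction = config$resampleFraction, seed = seed)
  else fitCumulativeJumps(jumps, nComponents = 3L)
  note("bound fraction: ", signif(diffFit@fB, 3))

  # --- fractions, search model, landscape ------------------------------
  fracs <- splitBoundFraction(diffFit@fB, spectrum, config$threshold,
                              sdFb = diffFit@sds[["fB"]])
  sds <- c(pF = fracs@sds[["pF"]], pU = fracs@sds[["pU"]],
           pS = fracs@sds[["pS"]],
           koffU = if (is.na(classes@sdTauU)) NA_real_ else
             classes@sdTauU / classes@tauU^2,
           kd = if (is.na(classes@sdTauS)) NA_real_ else
             classes@sdTauS / classes@tauS^2)
  smInput <- SearchModelInput(pF = fracs@pF, pU = fracs@pU, pS = fracs@pS,
                              koffU = classes@koffU, kd = classes@kd,
                              ratio = config$ratio, sds = sds)
  search <- solveRates(smInput)
  note("tau_search = ", signif(search@tauSearch, 4), " s")
  landscape <- energyLandscape(fracs, search)

  context <- list()
  if (!is.null(config$nSites) && !is.null(config$volumeUm3)) {
    context <- cellContext(
      moleculeCount = if (is.null(config$moleculeCount)) NA_real_ else
        config$moleculeCount,
      nSites = config$nSites, volumeUm3 = config$volumeUm3,
      kd = classes@kd, tauSearch = search@tauSearch)
  }

  new("VariantReport", name = config$name, spectrum = spectrum,
      classes = classes, diffusion = diffFit, fractions = fracs,
      search = search, landscape = landscape, context = context,
      provenance = list(seed = seed,
                        config = unclass(config),
                        package = "TrackKinetics",
                        version = as.character(
                          utils::packageVersion("TrackKinetics"))))
}

#' Run the pipeline for several variants
#'
#' Failures in one variant are recorded and do not abort the others.
#'
#' @param configs list of configurations
#' @param ... passed to [runPipeline()]
#' @return named list of [VariantReport-class] objects; failed variants
#'   carry the error condition instead
#' @export
runPipelines <- function(configs, ...) {
  out <- lapply(configs, function(cfg)
    tryCatch(runPipeline(cfg, ...), error = function(e) e))
  names(out) <- vapply(configs, `[[`, "", "name")
  nFail <- sum(vapply(out, inherits, TRUE, "error"))
  if (nFail > 0)
    warning(nFail, " variant(s) failed; their entries hold the error")
  out
}

#' Compare variant reports against a reference
#'
#' Builds the per-variant summary table: residence times, fractions,
#' search time, state-energy differences to the reference, and the
#' percent reduction in specific residence time.
#'
#' @param reports list of [VariantReport-class] objects
#' @param reference name of the reference variant (default `"WT"`)
#' @return data.frame, one row per variant
#' @export
compareVariants <- function(reports, reference = "WT") {
  reports <- Filter(function(r) is(r, "VariantReport"), reports)
  if (length(reports) < 2L) stop("need at least two successful reports")
  nms <- vapply(reports, function(r) r@name, "")
  if (!reference %in% nms)
    stop("reference variant '", reference, "' not among the reports")
  ref <- reports[[match(reference, nms)]]
  rows <- lapply(reports, function(r) {
    dd <- deltaDeltaG(r@fractions, ref@fractions)
    data.frame(
      variant = r@name,
      tau_s = r@classes@tauS, sd_tau_s = r@classes@sdTauS,
      tau_u = r@classes@tauU, sd_tau_u = r@classes@sdTauU,
      p_s = r@fractions@pS, p_u = r@fractions@pU,
      tau_search = r@search@tauSearch,
      ddG_s = dd[["ddGs"]], ddG_u = dd[["ddGu"]],
      sd_ddG_s = dd[["sdDdGs"]], sd_ddG_u = dd[["sdDdGu"]],
      tau_s_reduction_pct = residenceTimeReduction(ref@classes@tauS,
                                                   r@classes@tauS))
  })
  do.call(rbind, rows)
}

#' Percent reduction of a residence time relative to a reference
#'
#' @param tauRef reference residence time (s)
#' @param tauVariant variant residence time (s)
#' @return reduction in percent (positive = shorter than the reference)
#' @examples
#' residenceTimeReduction(247, 159)
#' @export
residenceTimeReduction <- function(tauRef, tauVariant) {
  if (tauRef <= 0) stop("tauRef must be > 0")
  100 * (1 - tauVariant / tauRef)
}
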