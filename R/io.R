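## Plain-text interchange: CSV for tracks and survival datasets, TSV for
## spectra and sweeps, JSON for ground-truth presets and reports.

#' Read and write track tables
#'
#' CSV with header `track_id,frame,x_um,y_um`.
#'
#' @param object a [TrackTable-class]
#' @param path file path
#' @param frameInterval frame interval in seconds attached on read
#' @return `readTrackTable` returns a [TrackTable-class];
#'   `writeTrackTable` returns `path` invisibly
#' @export
writeTrackTable <- function(object, path) {
  stopifnot(is(object, "TrackTable"))
  write.csv(object@tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path, frameInterval = NA_real_) {
  TrackTable(read.csv(path), frameInterval = frameInterval)
}

#' Read and write survival datasets
#'
#' CSV with header `condition_cycle_s,duration_s`, one row per observed
#' track, as emitted by the synthetic generator.
#'
#' @param durations named list of durations per condition
#' @param conditions list of [TimeLapseCondition-class] objects matching
#'   `durations`
#' @param path file path
#' @return `readSurvivalData` returns a list of duration vectors named by
#'   cycle time; `writeSurvivalData` returns `path` invisibly
#' @export
writeSurvivalData <- function(durations, conditions, path) {
  stopifnot(length(durations) == length(conditions))
  df <- do.call(rbind, lapply(seq_along(durations), function(i)
    data.frame(condition_cycle_s = conditions[[i]]@cycleTime,
               duration_s = durations[[i]])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSurvivalData
#' @export
readSurvivalData <- function(path) {
  df <- read.csv(path)
  split(df$duration_s, sprintf("tl_%gs", df$condition_cycle_s))
}

#' Write a dissociation spectrum as TSV plus JSON summary
#'
#' The TSV has columns `rate_per_s`, `event_amp`, `state_amp`; the JSON
#' sidecar (same path with extension `.json`) records the bleaching
#' number and fit residual.
#'
#' @param spectrum a [DissociationSpectrum-class]
#' @param path TSV path
#' @return `path` invisibly
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "DissociationSpectrum"))
  df <- data.frame(rate_per_s = spectrum@rateGrid,
                   event_amp = spectrum@eventAmps,
                   state_amp = spectrum@stateAmps)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(bleach_number = spectrum@bleachNumber,
         fit_residual = spectrum@fitResidual),
    sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save and load ground-truth presets as JSON
#'
#' Round-trips a spectrum/diffusion ground-truth pair (as returned by
#' [wtPreset()]) through a JSON file without loss.
#'
#' @param preset list with elements `spectrum`
#'   ([GroundTruthSpectrum-class]) and `diffusion`
#'   ([DiffusionGroundTruth-class])
#' @param path JSON path
#' @return `readPreset` returns the preset list; `writePreset` returns
#'   `path` invisibly
#' @export
writePreset <- function(preset, path) {
  s <- preset$spectrum
  d <- preset$diffusion
  jsonlite::write_json(list(
    spectrum = list(rates = s@rates, event_weights = s@eventWeights,
                    bleach_number = s@bleachNumber),
    diffusion = list(fractions = d@fractions, diff_coeffs = d@diffCoeffs,
                     loc_error = d@locError,
                     frame_interval = d@frameInterval,
                     mean_track_frames = d@meanTrackFrames,
                     n_tracks = d@nTracks, seed = d@seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePreset
#' @param path JSON path
#' @export
readPreset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    spectrum = new("GroundTruthSpectrum", rates = x$spectrum$rates,
                   eventWeights = x$spectrum$event_weights,
                   bleachNumber = x$spectrum$bleach_number),
    diffusion = DiffusionGroundTruth(
      fractions = x$diffusion$fractions,
      diffCoeffs = x$diffusion$diff_coeffs,
      locError = x$diffusion$loc_error,
      frameInterval = x$diffusion$frame_interval,
      meanTrackFrames = x$diffusion$mean_track_frames,
      nTracks = x$diffusion$n_tracks, seed = x$diffusion$seed))
}

## Flatten a VariantReport to plain lists for JSON serialization
.reportAsList <- function(report) {
  cl <- report@classes
  fr <- report@fractions
  se <- report@search
  la <- report@landscape
  r <- se@rates
  list(
    name = report@name,
    threshold = cl@threshold,
    k_d = cl@kd, koff_u = cl@koffU,
    tau_s = cl@tauS, tau_u = cl@tauU,
    sd_tau_s = cl@sdTauS, sd_tau_u = cl@sdTauU,
    p_f = fr@pF, p_u = fr@pU, p_s = fr@pS, f_b = fr@fB,
    bleach_number = report@spectrum@bleachNumber,
    diffusion = list(D = report@diffusion@diffCoeffs,
                     A = report@diffusion@fractions),
    rates = list(kon_u_star = r@konUStar, koff_u = r@koffU,
                 kon_s_star = r@konSStar, koff_s = r@koffS,
                 k_us = r@kUS, k_su = r@kSU),
    k_a_star = se@kAStar, tau_search = se@tauSearch,
    fold_acceleration = se@foldAcceleration,
    landscape = list(dG_u = la@dGu, dG_s = la@dGs, dG_f_u = la@dGfU,
                     dG_u_s = la@dGuS, dG_f_s = la@dGfS, k_A = la@kA),
    context = report@context,
    provenance = report@provenance)
}

#' Write a variant report as JSON
#'
#' Deterministic (no timestamps): identical reports serialize to
#' byte-identical files.
#'
#' @param report a [VariantReport-class]
#' @param path JSON path
#' @return `path` invisibly
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "VariantReport"))
  jsonlite::write_json(.reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
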