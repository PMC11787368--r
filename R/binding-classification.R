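## Partition of a dissociation-rate spectrum into specific (slow) and
## unspecific (fast) binding at a rate threshold, effective class rates,
## residence times, and the split of the overall bound fraction.

#' Classify grid rates as specific or unspecific
#'
#' Rates strictly below the threshold are specific; rates at or above it
#' are unspecific (the boundary itself is not "below" the threshold).
#' Only grid points carrying state amplitude above `minAmp` are assigned.
#'
#' @param spectrum a [DissociationSpectrum-class]
#' @param threshold classification threshold in 1/s (default 0.01)
#' @param minAmp amplitude floor below which a grid point is ignored
#' @return list with integer index vectors `specific` and `unspecific`;
#'   an empty class is reported with a warning
#' @examples
#' s <- DissociationSpectrum(c(5, 0.7, 0.02, 0.003), rep(0.25, 4))
#' classifyRates(s)$specific
#' @export
classifyRates <- function(spectrum, threshold = 0.01, minAmp = 1e-9) {
  stopifnot(is(spectrum, "DissociationSpectrum"))
  active <- which(spectrum@stateAmps > minAmp)
  spec <- active[spectrum@rateGrid[active] < threshold]
  unspec <- active[spectrum@rateGrid[active] >= threshold]
  if (length(spec) == 0L)
    warning("empty specific class: no dissociation rate below ",
            threshold, " 1/s carries amplitude")
  if (length(unspec) == 0L)
    warning("empty unspecific class: no dissociation rate at or above ",
            threshold, " 1/s carries amplitude")
  list(specific = as.integer(spec), unspecific = as.integer(unspec))
}

#' Effective (state-weighted) dissociation rate of a class
#'
#' Averages the grid rates over the given indices with weights equal to
#' the state amplitudes renormalized within the class: the snapshot
#' occupancy of each rate class is what an effective residence time
#' averages over.
#'
#' @param spectrum a [DissociationSpectrum-class]
#' @param indices grid indices of the class (from [classifyRates()])
#' @return effective dissociation rate in 1/s
#' @examples
#' s <- DissociationSpectrum(c(0.005, 0.002), c(0.6, 0.4),
#'                           fitResidual = 0)
#' 1 / weightedRate(s, 1:2)  # residence time
#' @export
weightedRate <- function(spectrum, indices) {
  stopifnot(is(spectrum, "DissociationSpectrum"))
  if (length(indices) == 0L)
    stop("cannot average an empty rate class")
  w <- spectrum@stateAmps[indices]
  if (sum(w) <= 0) stop("class carries no state amplitude")
  w <- w / sum(w)
  sum(w * spectrum@rateGrid[indices])
}

#' Classify a spectrum into binding classes with residence times
#'
#' Convenience wrapper: classifies, computes the effective specific and
#' unspecific dissociation rates and their inverse residence times, and,
#' if a resample set is given, their standard deviations across resamples.
#'
#' @param spectrum a [DissociationSpectrum-class]
#' @param threshold classification threshold in 1/s
#' @param resamples optional [SpectrumResampleSet-class] for uncertainties
#' @return a [BindingClasses-class]
#' @export
classifySpectrum <- function(spectrum, threshold = 0.01, resamples = NULL) {
  idx <- classifyRates(spectrum, threshold)
  kd <- if (length(idx$specific)) weightedRate(spectrum, idx$specific) else
    NA_real_
  ku <- if (length(idx$unspecific)) weightedRate(spectrum, idx$unspecific)
    else NA_real_
  sdS <- sdU <- NA_real_
  if (!is.null(resamples)) {
    stopifnot(is(resamples, "SpectrumResampleSet"))
    taus <- vapply(resamples@spectra, function(sp) {
      i <- suppressWarnings(classifyRates(sp, threshold))
      c(s = if (length(i$specific)) 1 / weightedRate(sp, i$specific) else
          NA_real_,
        u = if (length(i$unspecific)) 1 / weightedRate(sp, i$unspecific)
          else NA_real_)
    }, c(s = 1, u = 1))
    sdS <- sd(taus["s", ], na.rm = TRUE)
    sdU <- sd(taus["u", ], na.rm = TRUE)
  }
  new("BindingClasses", threshold = threshold, kd = kd, koffU = ku,
      tauS = 1 / kd, tauU = 1 / ku, sdTauS = sdS, sdTauU = sdU,
      specificIdx = idx$specific, unspecificIdx = idx$unspecific)
}

#' Split the overall bound fraction into state fractions
#'
#' The probability of finding a molecule bound in class l is the overall
#' bound fraction times that class's state amplitude; summing over the
#' specific and unspecific classes gives pS and pU, and pF = 1 - fB.
#'
#' @param fB overall bound fraction from the diffusion fit, in [0, 1]
#' @param spectrum a [DissociationSpectrum-class]
#' @param threshold classification threshold in 1/s
#' @param sdFb optional sd of fB, propagated proportionally
#' @return a [BindingFractions-class]
#' @examples
#' s <- DissociationSpectrum(c(1 / 0.9, 1 / 277), c(0.72, 0.28),
#'                           fitResidual = 0)
#' splitBoundFraction(0.37, s)
#' @export
splitBoundFraction <- function(fB, spectrum, threshold = 0.01,
                               sdFb = NA_real_) {
  if (fB < 0 || fB > 1) stop("fB must lie in [0, 1]")
  stopifnot(is(spectrum, "DissociationSpectrum"))
  sSpec <- sum(spectrum@stateAmps[spectrum@rateGrid < threshold])
  pS <- fB * sSpec
  pU <- fB * (1 - sSpec)
  sds <- c(pF = sdFb, pU = if (is.na(sdFb)) NA_real_ else sdFb * (1 - sSpec),
           pS = if (is.na(sdFb)) NA_real_ else sdFb * sSpec, fB = sdFb)
  BindingFractions(pF = 1 - fB, pU = pU, pS = pS, sds = sds)
}
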