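#' @import methods
#' @importFrom stats optimize optim uniroot rexp rgeom rnorm runif setNames
#'   ecdf quantile sd ave
#' @importFrom utils read.csv write.csv write.table head tail
NULL

.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    return(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lower) return(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper) return(sprintf("'%s' must be <= %g", name, upper))
  NULL
}

## ---- acquisition metadata -------------------------------------------------

#' Time-lapse acquisition condition
#'
#' Describes one time-lapse illumination scheme: a short camera exposure
#' repeated with a (possibly much longer) frame-cycle time. Varying the
#' frame-cycle time while keeping the exposure fixed decouples
#' photobleaching, which acts per acquired frame, from dissociation, which
#' acts per unit time.
#'
#' @slot cycleTime seconds per frame cycle
#' @slot integrationTime camera exposure in seconds (<= cycleTime)
#' @slot minTrackFrames minimum number of frames for a track to be counted
#' @slot maxGapFrames number of undetected frames a track may bridge
#' @slot movieDuration total movie length in seconds
#' @export
setClass("TimeLapseCondition",
  representation(cycleTime = "numeric", integrationTime = "numeric",
                 minTrackFrames = "integer", maxGapFrames = "integer",
                 movieDuration = "numeric"),
  validity = function(object) {
    msgs <- c(
      .check_scalar(object@cycleTime, "cycleTime", lower = 1e-12),
      .check_scalar(object@integrationTime, "integrationTime", lower = 1e-12),
      .check_scalar(object@movieDuration, "movieDuration", lower = 0))
    if (length(msgs)) return(msgs)
    if (object@integrationTime > object@cycleTime)
      return("integrationTime must not exceed cycleTime")
    if (object@minTrackFrames < 2L)
      return("minTrackFrames must be >= 2")
    if (object@maxGapFrames < 0L)
      return("maxGapFrames must be >= 0")
    if (object@movieDuration < object@cycleTime * object@minTrackFrames)
      return("movieDuration must cover at least minTrackFrames frame cycles")
    TRUE
  })

#' Construct a TimeLapseCondition
#'
#' @param cycleTime frame-cycle time in seconds
#' @param integrationTime camera integration time in seconds
#' @param minTrackFrames minimum track length in frames
#' @param maxGapFrames allowed gap frames
#' @param movieDuration movie length in seconds
#' @return a [TimeLapseCondition-class] object
#' @examples
#' TimeLapseCondition(0.4, 0.05, minTrackFrames = 3)
#' @export
TimeLapseCondition <- function(cycleTime, integrationTime = 0.05,
                               minTrackFrames = 2L, maxGapFrames = 1L,
                               movieDuration = cycleTime * 3000) {
  new("TimeLapseCondition", cycleTime = as.numeric(cycleTime),
      integrationTime = as.numeric(integrationTime),
      minTrackFrames = as.integer(minTrackFrames),
      maxGapFrames = as.integer(maxGapFrames),
      movieDuration = as.numeric(movieDuration))
}

## ---- ground truths for the generator --------------------------------------

#' Ground-truth dissociation-rate spectrum
#'
#' A finite mixture of exponential binding times: dissociation rates with
#' event weights (relative frequency of binding events per class) and a
#' per-frame photobleaching number. The fluorophore survives one acquired
#' frame with probability \code{exp(-bleachNumber)}.
#'
#' @slot rates dissociation rates in 1/s
#' @slot eventWeights event-spectrum weights, nonnegative, summing to 1
#' @slot bleachNumber per-frame bleaching propensity (dimensionless, >= 0)
#' @export
setClass("GroundTruthSpectrum",
  representation(rates = "numeric", eventWeights = "numeric",
                 bleachNumber = "numeric"),
  validity = function(object) {
    if (length(object@rates) < 1L || any(!is.finite(object@rates)) ||
        any(object@rates <= 0))
      return("rates must be positive and finite")
    if (length(object@eventWeights) != length(object@rates))
      return("eventWeights must match rates in length")
    if (any(object@eventWeights < 0))
      return("eventWeights must be nonnegative")
    if (abs(sum(object@eventWeights) - 1) > 1e-12)
      return("eventWeights must sum to 1 (tolerance 1e-12)")
    msg <- .check_scalar(object@bleachNumber, "bleachNumber", lower = 0)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' Construct a GroundTruthSpectrum
#'
#' Weights may be given on the event scale (default) or the state scale;
#' state weights are converted via the event/state relation
#' \eqn{A^e_l \propto A^s_l k_l}.
#'
#' @param rates dissociation rates (1/s)
#' @param weights mixture weights, summing to 1
#' @param bleachNumber per-frame bleaching propensity
#' @param weightType \code{"event"} or \code{"state"}
#' @return a [GroundTruthSpectrum-class]
#' @export
GroundTruthSpectrum <- function(rates, weights, bleachNumber = 0,
                                weightType = c("event", "state")) {
  weightType <- match.arg(weightType)
  w <- as.numeric(weights)
  if (weightType == "state") {
    w <- w * rates
    w <- w / sum(w)
  } else if (abs(sum(w) - 1) > 1e-12 && all(w >= 0) && sum(w) > 0) {
    stop("weights must sum to 1")
  }
  new("GroundTruthSpectrum", rates = as.numeric(rates), eventWeights = w,
      bleachNumber = as.numeric(bleachNumber))
}

#' Ground truth for a Brownian jump-distance mixture
#'
#' @slot fractions mixture fractions per diffusion component, summing to 1
#' @slot diffCoeffs diffusion coefficients in um^2/s, strictly increasing
#' @slot locError 1D localization error sigma in um, added per localization
#' @slot frameInterval frame interval in seconds
#' @slot meanTrackFrames mean of the geometric track-length law (frames)
#' @slot nTracks number of tracks to generate
#' @slot seed integer seed
#' @export
setClass("DiffusionGroundTruth",
  representation(fractions = "numeric", diffCoeffs = "numeric",
                 locError = "numeric", frameInterval = "numeric",
                 meanTrackFrames = "numeric", nTracks = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@fractions) != length(object@diffCoeffs))
      return("fractions and diffCoeffs must have equal length")
    if (any(object@fractions < 0) || abs(sum(object@fractions) - 1) > 1e-9)
      return("fractions must be nonnegative and sum to 1")
    if (is.unsorted(object@diffCoeffs, strictly = TRUE))
      return("diffCoeffs must be strictly increasing")
    if (any(object@diffCoeffs < 0))
      return("diffCoeffs must be nonnegative")
    if (object@locError < 0) return("locError must be >= 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    if (object@meanTrackFrames < 2) return("meanTrackFrames must be >= 2")
    if (object@nTracks < 0L) return("nTracks must be >= 0")
    TRUE
  })

#' Construct a DiffusionGroundTruth
#'
#' @param fractions mixture fractions (sum to 1)
#' @param diffCoeffs diffusion coefficients (um^2/s, ascending)
#' @param locError localization sigma (um)
#' @param frameInterval frame interval (s)
#' @param meanTrackFrames mean geometric track length in frames
#' @param nTracks number of tracks
#' @param seed integer seed
#' @return a [DiffusionGroundTruth-class]
#' @export
DiffusionGroundTruth <- function(fractions, diffCoeffs, locError = 0.035,
                                 frameInterval = 0.0117,
                                 meanTrackFrames = 20, nTracks = 1000L,
                                 seed = 1L) {
  new("DiffusionGroundTruth", fractions = as.numeric(fractions),
      diffCoeffs = as.numeric(diffCoeffs), locError = as.numeric(locError),
      frameInterval = as.numeric(frameInterval),
      meanTrackFrames = as.numeric(meanTrackFrames),
      nTracks = as.integer(nTracks), seed = as.integer(seed))
}

#' Rate set of the three-state chain free / unspecific / specific
#'
#' @slot konUStar pseudo-first-order unspecific association rate (1/s)
#' @slot koffU unspecific dissociation rate (1/s)
#' @slot konSStar pseudo-first-order direct specific association rate (1/s)
#' @slot koffS direct specific dissociation rate (1/s)
#' @slot kUS microscopic unspecific-to-specific transition rate (1/s)
#' @slot kSU microscopic specific-to-unspecific transition rate (1/s)
#' @export
setClass("ThreeStateRates",
  representation(konUStar = "numeric", koffU = "numeric",
                 konSStar = "numeric", koffS = "numeric",
                 kUS = "numeric", kSU = "numeric"),
  validity = function(object) {
    v <- c(object@konUStar, object@koffU, object@konSStar, object@koffS,
           object@kUS, object@kSU)
    if (length(v) != 6L || any(!is.finite(v)) || any(v < 0))
      return("all six rates must be finite and >= 0")
    TRUE
  })

#' Construct a ThreeStateRates
#' @param konUStar,koffU,konSStar,koffS,kUS,kSU rates in 1/s
#' @return a [ThreeStateRates-class]
#' @export
ThreeStateRates <- function(konUStar, koffU, konSStar, koffS, kUS, kSU) {
  new("ThreeStateRates", konUStar = konUStar, koffU = koffU,
      konSStar = konSStar, koffS = koffS, kUS = kUS, kSU = kSU)
}

## ---- track container ------------------------------------------------------

#' Single-molecule track table
#'
#' Localized trajectories: one row per localization with track id, frame
#' index and x/y position in micrometers.
#'
#' @slot tracks data.frame with columns track_id, frame, x_um, y_um
#' @slot frameInterval frame interval in seconds (NA if unknown)
#' @export
setClass("TrackTable",
  representation(tracks = "data.frame", frameInterval = "numeric"),
  validity = function(object) {
    need <- c("track_id", "frame", "x_um", "y_um")
    if (!all(need %in% names(object@tracks)))
      return(paste("tracks must have columns", paste(need, collapse = ", ")))
    if (nrow(object@tracks) &&
        (any(!is.finite(object@tracks$frame)) ||
         any(object@tracks$frame != floor(object@tracks$frame))))
      return("frame indices must be integers")
    TRUE
  })

#' Construct a TrackTable
#' @param tracks data.frame with columns track_id, frame, x_um, y_um
#' @param frameInterval frame interval in seconds
#' @return a [TrackTable-class]
#' @export
TrackTable <- function(tracks = data.frame(track_id = integer(),
                                           frame = integer(),
                                           x_um = numeric(),
                                           y_um = numeric()),
                       frameInterval = NA_real_) {
  new("TrackTable", tracks = tracks, frameInterval = as.numeric(frameInterval))
}

## ---- survival analysis ----------------------------------------------------

#' Survival-time histogram of track durations under one condition
#'
#' `counts[i]` is the number of tracks with duration at least `times[i]`,
#' so counts are non-increasing and `counts[1]` is the total event count.
#'
#' @slot condition the [TimeLapseCondition-class] the data were recorded under
#' @slot times duration grid in seconds (positive multiples of the cycle time)
#' @slot counts number of tracks surviving to each grid time
#' @export
setClass("SurvivalHistogram",
  representation(condition = "TimeLapseCondition", times = "numeric",
                 counts = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@counts))
      return("times and counts must have equal length")
    if (length(object@times) == 0L) return("histogram must not be empty")
    if (any(diff(object@counts) > 1e-9))
      return("counts must be non-increasing")
    if (any(object@times <= 0)) return("times must be positive")
    dt <- object@condition@cycleTime
    if (any(abs(object@times / dt - round(object@times / dt)) > 1e-6))
      return("times must be multiples of the cycle time")
    TRUE
  })

#' Dissociation-rate spectrum
#'
#' Event and state amplitudes over a fixed grid of dissociation rates plus
#' the globally shared per-frame bleaching number. Event amplitudes weight
#' classes by how often binding events occur; state amplitudes weight them
#' by snapshot occupancy and satisfy \eqn{A^s_l \propto A^e_l / k_l}.
#'
#' @slot rateGrid dissociation-rate grid (1/s)
#' @slot eventAmps event amplitudes, nonnegative, summing to 1
#' @slot stateAmps state amplitudes, nonnegative, summing to 1
#' @slot bleachNumber fitted per-frame bleaching propensity
#' @slot fitResidual weighted residual sum of squares of the fit
#' @export
setClass("DissociationSpectrum",
  representation(rateGrid = "numeric", eventAmps = "numeric",
                 stateAmps = "numeric", bleachNumber = "numeric",
                 fitResidual = "numeric"),
  validity = function(object) {
    n <- length(object@rateGrid)
    if (length(object@eventAmps) != n || length(object@stateAmps) != n)
      return("amplitude vectors must match the rate grid in length")
    if (any(object@rateGrid <= 0)) return("rate grid must be positive")
    if (any(object@eventAmps < -1e-12) || any(object@stateAmps < -1e-12))
      return("amplitudes must be nonnegative")
    if (abs(sum(object@eventAmps) - 1) > 1e-9)
      return("event amplitudes must sum to 1 (1e-9)")
    if (abs(sum(object@stateAmps) - 1) > 1e-9)
      return("state amplitudes must sum to 1 (1e-9)")
    st <- object@eventAmps / object@rateGrid
    st <- st / sum(st)
    if (max(abs(st - object@stateAmps)) > 1e-6)
      return("state amplitudes must be proportional to eventAmps/rateGrid")
    if (object@bleachNumber < 0) return("bleachNumber must be >= 0")
    TRUE
  })

#' Construct a DissociationSpectrum from event amplitudes
#' @param rateGrid rate grid (1/s)
#' @param eventAmps event amplitudes (normalized internally)
#' @param bleachNumber per-frame bleaching number
#' @param fitResidual residual of the producing fit
#' @return a [DissociationSpectrum-class]
#' @export
DissociationSpectrum <- function(rateGrid, eventAmps, bleachNumber = 0,
                                 fitResidual = NA_real_) {
  eventAmps <- pmax(eventAmps, 0)
  if (sum(eventAmps) <= 0) stop("all-zero amplitude vector")
  eventAmps <- eventAmps / sum(eventAmps)
  st <- eventAmps / rateGrid
  st <- st / sum(st)
  new("DissociationSpectrum", rateGrid = as.numeric(rateGrid),
      eventAmps = eventAmps, stateAmps = st,
      bleachNumber = as.numeric(bleachNumber),
      fitResidual = as.numeric(fitResidual))
}

#' Resampled set of dissociation spectra
#'
#' @slot spectra list of [DissociationSpectrum-class] objects
#' @slot resampleFraction fraction of survival times used per resample
#' @slot nResamples number of resamples
#' @slot seed integer seed
#' @export
setClass("SpectrumResampleSet",
  representation(spectra = "list", resampleFraction = "numeric",
                 nResamples = "integer", seed = "integer"),
  validity = function(object) {
    if (!all(vapply(object@spectra, is, TRUE, "DissociationSpectrum")))
      return("spectra must all be DissociationSpectrum objects")
    if (object@resampleFraction <= 0 || object@resampleFraction > 1)
      return("resampleFraction must be in (0, 1]")
    TRUE
  })

## ---- classification -------------------------------------------------------

#' Specific/unspecific partition of a rate spectrum
#'
#' @slot threshold classification threshold (1/s); rates strictly below it
#'   are specific, at or above unspecific
#' @slot kd effective specific dissociation rate (1/s)
#' @slot koffU effective unspecific dissociation rate (1/s)
#' @slot tauS,tauU residence times (s), inverses of the effective rates
#' @slot sdTauS,sdTauU standard deviations from resampling (NA if absent)
#' @slot specificIdx,unspecificIdx grid indices of each class
#' @export
setClass("BindingClasses",
  representation(threshold = "numeric", kd = "numeric", koffU = "numeric",
                 tauS = "numeric", tauU = "numeric",
                 sdTauS = "numeric", sdTauU = "numeric",
                 specificIdx = "integer", unspecificIdx = "integer"))

#' Free/unspecific/specific molecule fractions
#'
#' @slot pF,pU,pS probabilities of the free, unspecifically bound and
#'   specifically bound states; they sum to 1
#' @slot fB overall bound fraction, pU + pS
#' @slot sds named numeric of standard deviations (pF, pU, pS, fB)
#' @export
setClass("BindingFractions",
  representation(pF = "numeric", pU = "numeric", pS = "numeric",
                 fB = "numeric", sds = "numeric"),
  validity = function(object) {
    p <- c(object@pF, object@pU, object@pS)
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      return("fractions must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) return("pF + pU + pS must equal 1 (1e-9)")
    if (abs(object@fB - (object@pU + object@pS)) > 1e-9)
      return("fB must equal pU + pS")
    TRUE
  })

#' Construct a BindingFractions
#' @param pF,pU,pS state probabilities (must sum to 1)
#' @param sds optional named sds for pF, pU, pS, fB
#' @return a [BindingFractions-class]
#' @export
BindingFractions <- function(pF, pU, pS,
                             sds = c(pF = NA_real_, pU = NA_real_,
                                     pS = NA_real_, fB = NA_real_)) {
  new("BindingFractions", pF = pF, pU = pU, pS = pS, fB = pU + pS, sds = sds)
}

## ---- jump-distance analysis -----------------------------------------------

#' Jump-distance dataset
#'
#' @slot jumps per-frame displacement magnitudes (um)
#' @slot frameInterval frame interval (s)
#' @slot firstJumpsOnly whether the first-jumps-per-track rule was applied
#' @slot gapJumpsExcluded whether gap-spanning jumps were dropped
#' @export
setClass("JumpDataset",
  representation(jumps = "numeric", frameInterval = "numeric",
                 firstJumpsOnly = "logical", gapJumpsExcluded = "logical"),
  validity = function(object) {
    if (any(object@jumps < 0)) return("jumps must be >= 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    TRUE
  })

#' Brownian mixture fit to a cumulative jump-distance distribution
#'
#' @slot nComponents number of diffusion components (2 or 3; 1 for checks)
#' @slot diffCoeffs fitted diffusion coefficients (um^2/s, ascending)
#' @slot fractions fitted fractions, summing to 1
#' @slot fB bound fraction = fraction of the slowest component
#' @slot sds named sds from resampling (NA if absent)
#' @slot residual residual sum of squares on the evaluation grid
#' @slot nJumps number of jumps fitted
#' @slot degenerate TRUE if two components collapsed within 5 percent in D
#' @export
setClass("DiffusionFit",
  representation(nComponents = "integer", diffCoeffs = "numeric",
                 fractions = "numeric", fB = "numeric", sds = "numeric",
                 residual = "numeric", nJumps = "integer",
                 degenerate = "logical"),
  validity = function(object) {
    if (length(object@diffCoeffs) != object@nComponents ||
        length(object@fractions) != object@nComponents)
      return("parameter vectors must match nComponents")
    if (abs(sum(object@fractions) - 1) > 1e-9)
      return("fractions must sum to 1 (1e-9)")
    if (is.unsorted(object@diffCoeffs)) return("diffCoeffs must be ascending")
    if (object@fB < 0 || object@fB > 1) return("fB must be in [0, 1]")
    TRUE
  })

## ---- search model ---------------------------------------------------------

#' Inputs to the three-state facilitated-diffusion solver
#'
#' One closure is required because only five of the seven model parameters
#' are measurable: either the ratio \code{koffS/kd} in (0, 1] or a direct
#' specific association rate konSStar.
#'
#' @slot pF,pU,pS state fractions, all positive, summing to 1
#' @slot koffU unspecific dissociation rate (1/s)
#' @slot kd effective specific dissociation rate (1/s), < koffU
#' @slot ratio closure ratio koffS/kd (NA if konSStar given)
#' @slot konSStar closure direct association rate (NA if ratio given)
#' @slot sds named sds of (pF, pU, pS, koffU, kd) for error propagation
#' @export
setClass("SearchModelInput",
  representation(pF = "numeric", pU = "numeric", pS = "numeric",
                 koffU = "numeric", kd = "numeric", ratio = "numeric",
                 konSStar = "numeric", sds = "numeric"),
  validity = function(object) {
    p <- c(object@pF, object@pU, object@pS)
    if (any(p <= 0)) return("pF, pU, pS must all be > 0")
    if (abs(sum(p) - 1) > 1e-9) return("pF + pU + pS must equal 1")
    if (object@koffU <= 0 || object@kd <= 0)
      return("koffU and kd must be > 0")
    if (object@kd >= object@koffU)
      return(paste("kd must be smaller than koffU: the effective specific",
                   "dissociation rate cannot exceed the unspecific one in",
                   "this model"))
    if (is.na(object@ratio) == is.na(object@konSStar))
      return("exactly one closure (ratio or konSStar) must be given")
    if (!is.na(object@ratio) && (object@ratio <= 0 || object@ratio > 1))
      return("closure ratio koffS/kd must lie in (0, 1]")
    TRUE
  })

#' Construct a SearchModelInput
#' @param pF,pU,pS state fractions
#' @param koffU unspecific dissociation rate (1/s)
#' @param kd effective specific dissociation rate (1/s)
#' @param ratio closure ratio koffS/kd in (0, 1]
#' @param konSStar alternative closure: direct specific association rate
#' @param sds optional named sds (pF, pU, pS, koffU, kd)
#' @return a [SearchModelInput-class]
#' @export
SearchModelInput <- function(pF, pU, pS, koffU, kd, ratio = 0.0705,
                             konSStar = NA_real_,
                             sds = c(pF = NA_real_, pU = NA_real_,
                                     pS = NA_real_, koffU = NA_real_,
                                     kd = NA_real_)) {
  if (!is.na(konSStar)) ratio <- NA_real_
  new("SearchModelInput", pF = pF, pU = pU, pS = pS, koffU = koffU, kd = kd,
      ratio = as.numeric(ratio), konSStar = as.numeric(konSStar), sds = sds)
}

#' Solved three-state search model
#'
#' @slot rates the full [ThreeStateRates-class]
#' @slot kAStar effective specific association rate (1/s)
#' @slot tauSearch target-site search time (s), 1/kAStar
#' @slot sdTauSearch propagated sd of tauSearch (NA if no input sds)
#' @slot foldAcceleration kAStar / konSStar
#' @slot input the [SearchModelInput-class] that produced the result
#' @export
setClass("SearchModelResult",
  representation(rates = "ThreeStateRates", kAStar = "numeric",
                 tauSearch = "numeric", sdTauSearch = "numeric",
                 foldAcceleration = "numeric", input = "SearchModelInput"))

## ---- energy landscape -----------------------------------------------------

#' Effective in vivo binding-energy landscape
#'
#' State energies are relative to the free state; transition barriers are
#' relative to an arbitrary frequency factor kA, so only barrier
#' differences are physically meaningful. All energies are in units of
#' thermal energy (kB*T) and dimensionless.
#'
#' @slot dGu,dGs state energies of unspecific and specific binding (kB*T)
#' @slot dGfU,dGuS,dGfS transition barriers free->unspecific,
#'   unspecific->specific and free->specific, relative to kA (kB*T)
#' @slot kA frequency-factor convention (1/s)
#' @slot sds named sds of the five energies (NA where unavailable)
#' @export
setClass("EnergyLandscape",
  representation(dGu = "numeric", dGs = "numeric", dGfU = "numeric",
                 dGuS = "numeric", dGfS = "numeric", kA = "numeric",
                 sds = "numeric"),
  validity = function(object) {
    if (object@kA <= 0) return("kA must be > 0")
    TRUE
  })

## ---- cell context ---------------------------------------------------------

#' Nuclear geometry as an ellipsoid
#'
#' Axes may be given as semi-axes (volume 4/3*pi*a*b*c) or as diameters
#' (volume pi/6*d1*d2*d3); the conventions agree when d = 2a.
#'
#' @slot axes three axis lengths (um)
#' @slot convention "semi-axes" or "diameters"
#' @slot volume ellipsoid volume (um^3)
#' @export
setClass("NuclearGeometry",
  representation(axes = "numeric", convention = "character",
                 volume = "numeric"),
  validity = function(object) {
    if (length(object@axes) != 3L || any(object@axes <= 0))
      return("axes must be three positive lengths")
    if (!object@convention %in% c("semi-axes", "diameters"))
      return("convention must be 'semi-axes' or 'diameters'")
    v <- if (object@convention == "semi-axes")
      4 / 3 * pi * prod(object@axes) else pi / 6 * prod(object@axes)
    if (abs(v - object@volume) > 1e-6 * v)
      return("volume inconsistent with axes and convention")
    TRUE
  })

## ---- pipeline report ------------------------------------------------------

#' Per-variant pipeline report
#'
#' Bundles the stage outputs for one protein variant so variants can be
#' compared and serialized.
#'
#' @slot name variant label
#' @slot spectrum [DissociationSpectrum-class]
#' @slot classes [BindingClasses-class]
#' @slot diffusion [DiffusionFit-class]
#' @slot fractions [BindingFractions-class]
#' @slot search [SearchModelResult-class]
#' @slot landscape [EnergyLandscape-class]
#' @slot context list of cell-context numbers (possibly empty)
#' @slot provenance list: seed, configuration, package version
#' @export
setClass("VariantReport",
  representation(name = "character", spectrum = "DissociationSpectrum",
                 classes = "BindingClasses", diffusion = "DiffusionFit",
                 fractions = "BindingFractions", search = "SearchModelResult",
                 landscape = "EnergyLandscape", context = "list",
                 provenance = "list"))
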