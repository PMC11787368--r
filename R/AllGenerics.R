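#' Accessor generics
#'
#' Small accessor family for the kinetic data classes: rate grids,
#' amplitudes, fractions, rates and times are read through these rather
#' than by slot access.
#'
#' @param object an object of one of the package classes
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rateGrid", function(object) standardGeneric("rateGrid"))
#' @rdname accessors
#' @export
setGeneric("eventAmps", function(object) standardGeneric("eventAmps"))
#' @rdname accessors
#' @export
setGeneric("stateAmps", function(object) standardGeneric("stateAmps"))
#' @rdname accessors
#' @export
setGeneric("bleachNumber", function(object) standardGeneric("bleachNumber"))
#' @rdname accessors
#' @export
setGeneric("boundFraction", function(object) standardGeneric("boundFraction"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("diffCoeffs", function(object) standardGeneric("diffCoeffs"))
#' @rdname accessors
#' @export
setGeneric("tauSearch", function(object) standardGeneric("tauSearch"))
#' @rdname accessors
#' @export
setGeneric("residenceTimes", function(object) standardGeneric("residenceTimes"))
#' @rdname accessors
#' @export
setGeneric("threeStateRates", function(object) standardGeneric("threeStateRates"))
#' @rdname accessors
#' @export
setGeneric("trackData", function(object) standardGeneric("trackData"))
#' @rdname accessors
#' @export
setGeneric("cycleTime", function(object) standardGeneric("cycleTime"))
#' @rdname accessors
#' @export
setGeneric("stateEnergyValues", function(object) standardGeneric("stateEnergyValues"))
#' @rdname accessors
#' @export
setGeneric("barrierValues", function(object) standardGeneric("barrierValues"))

setMethod("rateGrid", "DissociationSpectrum", function(object) object@rateGrid)
setMethod("eventAmps", "DissociationSpectrum", function(object) object@eventAmps)
setMethod("stateAmps", "DissociationSpectrum", function(object) object@stateAmps)
setMethod("bleachNumber", "DissociationSpectrum",
          function(object) object@bleachNumber)
setMethod("bleachNumber", "GroundTruthSpectrum",
          function(object) object@bleachNumber)
setMethod("boundFraction", "DiffusionFit", function(object) object@fB)
setMethod("boundFraction", "BindingFractions", function(object) object@fB)
setMethod("fractions", "DiffusionFit", function(object) object@fractions)
setMethod("fractions", "BindingFractions",
          function(object) c(pF = object@pF, pU = object@pU, pS = object@pS))
setMethod("diffCoeffs", "DiffusionFit", function(object) object@diffCoeffs)
setMethod("tauSearch", "SearchModelResult", function(object) object@tauSearch)
setMethod("residenceTimes", "BindingClasses",
          function(object) c(tauS = object@tauS, tauU = object@tauU))
setMethod("threeStateRates", "SearchModelResult", function(object) object@rates)
setMethod("trackData", "TrackTable", function(object) object@tracks)
setMethod("cycleTime", "TimeLapseCondition", function(object) object@cycleTime)
setMethod("stateEnergyValues", "EnergyLandscape",
          function(object) c(dGu = object@dGu, dGs = object@dGs))
setMethod("barrierValues", "EnergyLandscape",
          function(object) c(dGfU = object@dGfU, dGuS = object@dGuS,
                             dGfS = object@dGfS))
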