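## show() methods for the central classes

setMethod("show", "TimeLapseCondition", function(object) {
  cat(sprintf(
    "TimeLapseCondition: cycle %g s, integration %g s, >= %d frames\n",
    object@cycleTime, object@integrationTime, object@minTrackFrames))
})

setMethod("show", "GroundTruthSpectrum", function(object) {
  cat("GroundTruthSpectrum with", length(object@rates), "class(es)\n")
  cat("  rates (1/s):  ", paste(signif(object@rates, 4), collapse = ", "),
      "\n")
  cat("  event weights:", paste(signif(object@eventWeights, 4),
                                collapse = ", "), "\n")
  cat("  bleach number:", object@bleachNumber, "per frame\n")
})

setMethod("show", "TrackTable", function(object) {
  n <- length(unique(object@tracks$track_id))
  cat(sprintf("TrackTable: %d tracks, %d localizations", n,
              nrow(object@tracks)))
  if (!is.na(object@frameInterval))
    cat(sprintf(", frame interval %g s", object@frameInterval))
  cat("\n")
})

setMethod("show", "DissociationSpectrum", function(object) {
  active <- which(object@eventAmps > 1e-6)
  cat(sprintf(
    "DissociationSpectrum: %d-point grid [%g, %g] 1/s, %d active point(s)\n",
    length(object@rateGrid), min(object@rateGrid), max(object@rateGrid),
    length(active)))
  cat(sprintf("  bleach number %.4g per frame, residual %.4g\n",
              object@bleachNumber, object@fitResidual))
  if (length(active) && length(active) <= 10) {
    cat("  rate (1/s)  event amp  state amp\n")
    for (i in active)
      cat(sprintf("  %9.4g  %9.4f  %9.4f\n", object@rateGrid[i],
                  object@eventAmps[i], object@stateAmps[i]))
  }
})

setMethod("show", "BindingClasses", function(object) {
  cat(sprintf("BindingClasses at threshold %g 1/s\n", object@threshold))
  cat(sprintf("  specific:   k_d = %.4g 1/s, tau_s = %.4g s", object@kd,
              object@tauS))
  if (!is.na(object@sdTauS)) cat(sprintf(" (sd %.3g)", object@sdTauS))
  cat("\n")
  cat(sprintf("  unspecific: k_off,u = %.4g 1/s, tau_u = %.4g s",
              object@koffU, object@tauU))
  if (!is.na(object@sdTauU)) cat(sprintf(" (sd %.3g)", object@sdTauU))
  cat("\n")
})

setMethod("show", "BindingFractions", function(object) {
  cat(sprintf(
    "BindingFractions: p_f = %.3f, p_u = %.3f, p_s = %.3f (f_b = %.3f)\n",
    object@pF, object@pU, object@pS, object@fB))
})

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf("DiffusionFit: %d component(s) on %d jumps%s\n",
              object@nComponents, object@nJumps,
              if (object@degenerate) " [degenerate]" else ""))
  cat("  D (um^2/s):", paste(signif(object@diffCoeffs, 3),
                             collapse = ", "), "\n")
  cat("  fractions: ", paste(signif(object@fractions, 3),
                             collapse = ", "), "\n")
  cat(sprintf("  bound fraction f_b = %.3f\n", object@fB))
})

setMethod("show", "ThreeStateRates", function(object) {
  cat("ThreeStateRates (1/s):\n")
  cat(sprintf("  kon_u* = %.4g, koff_u = %.4g\n", object@konUStar,
              object@koffU))
  cat(sprintf("  kon_s* = %.4g, koff_s = %.4g\n", object@konSStar,
              object@koffS))
  cat(sprintf("  k_u-s  = %.4g, k_s-u  = %.4g\n", object@kUS, object@kSU))
})

setMethod("show", "SearchModelResult", function(object) {
  cat("SearchModelResult\n")
  show(object@rates)
  cat(sprintf("  k_a* = %.4g 1/s, tau_search = %.4g s", object@kAStar,
              object@tauSearch))
  if (!is.na(object@sdTauSearch))
    cat(sprintf(" (sd %.3g)", object@sdTauSearch))
  cat(sprintf("\n  fold acceleration over direct association: %.3g\n",
              object@foldAcceleration))
})

setMethod("show", "EnergyLandscape", function(object) {
  cat("EnergyLandscape (kB*T units)\n")
  cat(sprintf("  states:   dG_u = %.3f, dG_s = %.3f\n", object@dGu,
              object@dGs))
  cat(sprintf(
    "  barriers (relative to kA = %g 1/s): f->u %.3f, u->s %.3f, f->s %.3f\n",
    object@kA, object@dGfU, object@dGuS, object@dGfS))
})

setMethod("show", "VariantReport", function(object) {
  cat("VariantReport:", object@name, "\n")
  show(object@classes)
  show(object@fractions)
  cat(sprintf("  tau_search = %.4g s\n", object@search@tauSearch))
})
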