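## Effective in vivo binding-energy landscape. State energies follow from
## occupancy ratios, dG = -ln(p_bound / p_free) in units of kB*T, at the
## binding-site concentrations actually present in the nucleus. Barrier
## heights follow from kinetic rates relative to an arbitrary common
## frequency factor kA, so only barrier differences are interpretable.

#' State energies from occupancy fractions
#'
#' \eqn{\Delta G_u = -\ln(p_u/p_f)} and \eqn{\Delta G_s = -\ln(p_s/p_f)}
#' in units of kB*T. Positive values mean the bound state lies above the
#' free state, i.e. binding is thermodynamically disfavored at nuclear
#' binding-site concentrations. Equivalently computable from rate ratios
#' (konUStar/koffU, konSStar/koffS) of a solved search model.
#'
#' @param fractions a [BindingFractions-class], or a
#'   [SearchModelResult-class] whose solved rate ratios are used
#' @return named numeric `c(dGu, dGs)` in kB*T
#' @examples
#' stateEnergies(BindingFractions(0.6, 0.3, 0.1))
#' @export
stateEnergies <- function(fractions) {
  if (is(fractions, "SearchModelResult")) {
    r <- fractions@rates
    if (r@konUStar <= 0 || r@konSStar <= 0)
      stop("zero association rate gives an infinite state energy")
    return(c(dGu = -log(r@konUStar / r@koffU),
             dGs = -log(r@konSStar / r@koffS)))
  }
  stopifnot(is(fractions, "BindingFractions"))
  if (fractions@pF <= 0 || fractions@pU <= 0 || fractions@pS <= 0)
    stop("zero state fraction gives an infinite state energy")
  c(dGu = -log(fractions@pU / fractions@pF),
    dGs = -log(fractions@pS / fractions@pF))
}

#' Transition barriers from kinetic rates
#'
#' Relative barrier heights assuming one common frequency factor kA for
#' all transitions: \eqn{\Delta G_{f\to u} = -\ln(k^*_{on,u}/k_A)},
#' \eqn{\Delta G_{u\to s} = -\ln(k_{u-s}/k_A) + \Delta G_{f\to u}} and
#' \eqn{\Delta G_{f\to s} = -\ln(k^*_{on,s}/k_A)}. Changing kA shifts all
#' barriers by the same additive constant, leaving differences invariant.
#'
#' @param result a [SearchModelResult-class] or [ThreeStateRates-class]
#' @param kA frequency factor in 1/s (default 1; recorded, not physical)
#' @return named numeric `c(dGfU, dGuS, dGfS)` in kB*T relative to kA
#' @export
barriers <- function(result, kA = 1) {
  r <- if (is(result, "SearchModelResult")) result@rates else result
  stopifnot(is(r, "ThreeStateRates"))
  if (kA <= 0) stop("kA must be > 0")
  if (r@konUStar <= 0 || r@konSStar <= 0 || r@kUS <= 0)
    stop("zero rate gives an infinite barrier")
  dGfU <- -log(r@konUStar / kA)
  c(dGfU = dGfU, dGuS = -log(r@kUS / kA) + dGfU,
    dGfS = -log(r@konSStar / kA))
}

#' Assemble a full energy landscape
#'
#' @param fractions a [BindingFractions-class]
#' @param result a [SearchModelResult-class] for the barriers
#' @param kA frequency-factor convention (1/s)
#' @param sds optional named sds for the five energies (else propagated
#'   from the fraction sds via [propagateEnergyErrors()] where possible)
#' @return an [EnergyLandscape-class]
#' @export
energyLandscape <- function(fractions, result, kA = 1, sds = NULL) {
  st <- stateEnergies(fractions)
  ba <- barriers(result, kA)
  if (is.null(sds)) {
    es <- propagateEnergyErrors(fractions)
    sds <- c(es, dGfU = NA_real_, dGuS = NA_real_, dGfS = NA_real_)
  }
  new("EnergyLandscape", dGu = st[["dGu"]], dGs = st[["dGs"]],
      dGfU = ba[["dGfU"]], dGuS = ba[["dGuS"]], dGfS = ba[["dGfS"]],
      kA = kA, sds = sds)
}

#' Variant-versus-reference energy differences
#'
#' \eqn{\Delta\Delta G = \Delta G(\mathrm{variant}) -
#' \Delta G(\mathrm{reference})}; positive values mean the variant binds
#' more weakly. Accepts landscapes or fractions. Barrier differences
#' require both landscapes to use the same kA convention.
#'
#' @param variant,reference [EnergyLandscape-class] or
#'   [BindingFractions-class] objects
#' @return named numeric with `ddGs`, `ddGu` and, when available, their
#'   sds `sdDdGs`, `sdDdGu`
#' @examples
#' wt <- BindingFractions(0.63, 0.272, 0.098)
#' mut <- BindingFractions(0.7522, 0.1989, 0.049)  # pS/pF halved
#' deltaDeltaG(mut, wt)[["ddGs"]]
#' @export
deltaDeltaG <- function(variant, reference) {
  asLand <- function(x) {
    if (is(x, "EnergyLandscape"))
      list(e = c(dGu = x@dGu, dGs = x@dGs), kA = x@kA,
           sds = x@sds[c("dGu", "dGs")])
    else {
      e <- stateEnergies(x)
      list(e = e, kA = NA_real_, sds = propagateEnergyErrors(x))
    }
  }
  v <- asLand(variant)
  w <- asLand(reference)
  if (!is.na(v$kA) && !is.na(w$kA) && v$kA != w$kA)
    stop("mixed frequency-factor conventions: recompute with a common kA")
  out <- c(ddGs = v$e[["dGs"]] - w$e[["dGs"]],
           ddGu = v$e[["dGu"]] - w$e[["dGu"]])
  sdd <- sqrt(v$sds^2 + w$sds^2)
  c(out, sdDdGs = unname(sdd["dGs"]), sdDdGu = unname(sdd["dGu"]))
}

#' Gaussian error propagation for state energies
#'
#' First-order propagation of fraction uncertainties into the state
#' energies: for \eqn{\Delta G = -\ln(x/y)} with independent x, y,
#' \eqn{sd(\Delta G) = \sqrt{(sd_x/x)^2 + (sd_y/y)^2}}. Given a resample
#' set of spectra plus a bound fraction, the empirical spread across
#' resamples is used instead.
#'
#' @param fractions a [BindingFractions-class] (sds taken from its `sds`
#'   slot), or a list of [BindingFractions-class] resample members
#' @return named numeric `c(dGu, dGs)` of standard deviations (kB*T)
#' @export
propagateEnergyErrors <- function(fractions) {
  if (is.list(fractions)) {
    e <- vapply(fractions, stateEnergies, c(dGu = 1, dGs = 1))
    return(c(dGu = sd(e["dGu", ]), dGs = sd(e["dGs", ])))
  }
  stopifnot(is(fractions, "BindingFractions"))
  s <- fractions@sds
  relF <- s[["pF"]] / fractions@pF
  c(dGu = sqrt((s[["pU"]] / fractions@pU)^2 + relF^2),
    dGs = sqrt((s[["pS"]] / fractions@pS)^2 + relF^2))
}
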