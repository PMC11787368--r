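## Cellular-scale arithmetic: nuclear volumes, molecule counts to molar
## concentrations, and the effective in vivo dissociation constant
## K_d = k_d * [binding sites] / k*_a obtained from the kinetic outputs.

.AVOGADRO <- 6.02214076e23

#' Ellipsoid volume under either axis convention
#'
#' Nuclear volumes are quoted either from semi-axes (4/3*pi*a*b*c) or
#' from diameters (pi/6*d1*d2*d3); both conventions are first-class and
#' agree when d = 2a.
#'
#' @param axes three axis lengths in um
#' @param convention `"semi-axes"` or `"diameters"`
#' @return a [NuclearGeometry-class]; use [ellipsoidVolume()] for the
#'   bare number
#' @export
nuclearGeometry <- function(axes, convention = c("semi-axes", "diameters")) {
  convention <- match.arg(convention)
  if (length(axes) != 3L || any(axes <= 0))
    stop("axes must be three positive lengths")
  v <- if (convention == "semi-axes") 4 / 3 * pi * prod(axes) else
    pi / 6 * prod(axes)
  new("NuclearGeometry", axes = as.numeric(axes), convention = convention,
      volume = v)
}

#' @rdname nuclearGeometry
#' @examples
#' ellipsoidVolume(c(12, 8, 3), "semi-axes")   # 1206.4 um^3
#' ellipsoidVolume(c(8, 8, 5), "diameters")    # 167.6 um^3
#' @export
ellipsoidVolume <- function(axes, convention = c("semi-axes", "diameters")) {
  nuclearGeometry(axes, convention)@volume
}

#' Molar concentration from a molecule count and a volume
#'
#' @param count number of molecules
#' @param volumeUm3 volume in um^3
#' @return concentration in mol/L
#' @examples
#' concentrationFromCount(193718, ellipsoidVolume(c(8, 8, 5), "diameters"))
#' @export
concentrationFromCount <- function(count, volumeUm3) {
  if (count < 0) stop("count must be >= 0")
  if (volumeUm3 <= 0) stop("volume must be > 0")
  count / (.AVOGADRO * volumeUm3 * 1e-15)  # 1 um^3 = 1e-15 L
}

#' Effective in vivo dissociation constant
#'
#' From the effective specific dissociation rate, the target-site search
#' time (inverse effective association rate) and the nuclear binding-site
#' concentration: \eqn{K_d = k_d [\mathrm{sites}] / k^*_a =
#' k_d [\mathrm{sites}] \tau_{search}}.
#'
#' @param kd effective specific dissociation rate (1/s)
#' @param tauSearch target-site search time (s)
#' @param nSites number of specific binding sites in the nucleus
#' @param volumeUm3 nuclear volume in um^3
#' @return dissociation constant in mol/L
#' @examples
#' inVivoKd(1 / 247, 2270, 15111,
#'          ellipsoidVolume(c(12, 8, 3), "semi-axes")) * 1e9  # nM
#' @export
inVivoKd <- function(kd, tauSearch, nSites, volumeUm3) {
  if (kd <= 0 || tauSearch <= 0 || nSites <= 0)
    stop("kd, tauSearch and nSites must be > 0")
  kd * concentrationFromCount(nSites, volumeUm3) * tauSearch
}

#' Total molecule count from a tagged count and an overexpression fold
#'
#' Tagged molecules overexpressed `fold`-fold relative to the endogenous
#' protein imply `endogenous = tagged / fold` and
#' `total = tagged + endogenous`. The endogenous count may also be given
#' directly, bypassing the fold.
#'
#' @param taggedCount measured tagged-molecule count
#' @param fold overexpression factor (> 0)
#' @param endogenousCount optional direct endogenous count
#' @return named numeric `c(endogenous, total)`
#' @examples
#' totalMolecules(90863, endogenousCount = 102855)
#' @export
totalMolecules <- function(taggedCount, fold = NULL,
                           endogenousCount = NULL) {
  if (is.null(endogenousCount)) {
    if (is.null(fold) || fold <= 0) stop("fold must be > 0")
    endogenousCount <- taggedCount / fold
  }
  c(endogenous = endogenousCount, total = taggedCount + endogenousCount)
}

#' Cell-context summary
#'
#' @param moleculeCount total molecule count in the nucleus
#' @param nSites number of specific binding sites
#' @param volumeUm3 nuclear volume (um^3)
#' @param kd effective specific dissociation rate (1/s)
#' @param tauSearch target-site search time (s)
#' @return named list: concentration (M), siteConcentration (M), Kd (M)
#' @export
cellContext <- function(moleculeCount, nSites, volumeUm3, kd, tauSearch) {
  list(moleculeCount = moleculeCount, nSites = nSites,
       volumeUm3 = volumeUm3,
       concentration = concentrationFromCount(moleculeCount, volumeUm3),
       siteConcentration = concentrationFromCount(nSites, volumeUm3),
       Kd = inVivoKd(kd, tauSearch, nSites, volumeUm3))
}
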