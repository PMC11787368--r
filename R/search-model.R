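## Three-state facilitated-diffusion model of target-site search.
##
## States: free (f), unspecifically bound (u), specifically bound (s),
## with rates konUStar (f->u), koffU (u->f), konSStar (f->s), koffS
## (s->f), kUS (u->s), kSU (s->u). Measurable are the stationary
## fractions (pF, pU, pS), the unspecific dissociation rate koffU and the
## effective specific dissociation rate kd = 1/tauS; one closure (the
## ratio koffS/kd, or a direct association rate konSStar) determines the
## remaining microscopic rates through detailed balance. The target-site
## search time is the mean first-passage time from free to specific,
## tauSearch = (konUStar + koffU + kUS) /
##             (konSStar*koffU + (konSStar + konUStar)*kUS).

#' Unspecific association rate from stationary fractions
#'
#' At stationarity the flux balance of the unspecific state gives
#' \eqn{k^*_{on,u} = (p_u / p_f) k_{off,u}}.
#'
#' @param pU,pF unspecific and free fractions (pF > 0)
#' @param koffU unspecific dissociation rate (1/s)
#' @return the pseudo-first-order unspecific association rate (1/s)
#' @examples
#' unspecificOnRate(0.3, 0.6, 1.0)
#' @export
unspecificOnRate <- function(pU, pF, koffU) {
  if (pF <= 0) stop("pF must be > 0")
  if (pU < 0 || koffU < 0) stop("pU and koffU must be >= 0")
  pU / pF * koffU
}

## Closed-form search time of the three-state chain (MFPT free -> specific)
.tauSearchFormula <- function(konUStar, koffU, konSStar, kUS) {
  den <- konSStar * koffU + (konSStar + konUStar) * kUS
  if (den <= 0) stop("no association pathway: search time undefined")
  (konUStar + koffU + kUS) / den
}

.solveRatesCore <- function(pF, pU, pS, koffU, kd, koffS) {
  konSStar <- pS / pF * koffS
  konUStar <- pU / pF * koffU
  if (abs(koffS - kd) / kd < 1e-12) {
    # pure direct pathway: no u <-> s exchange
    kUS <- 0
    kSU <- 0
  } else {
    x <- (kd / koffS - 1) * konSStar * koffU / konUStar
    kUS <- (kd - koffU) * x / ((kd - koffU) + x)
    if (!is.finite(kUS) || kUS < 0)
      stop("unphysical parameter combination: negative u->s rate")
    # detailed balance around the cycle fixes the reverse rate
    kSU <- kUS * (konUStar / koffU) * (koffS / konSStar)
  }
  list(konUStar = konUStar, koffU = koffU, konSStar = konSStar,
       koffS = koffS, kUS = kUS, kSU = kSU)
}

## invert the u->s closure relation: the effective specific dissociation
## rate kd solving  kUS = A*B/(A+B)  with  A = kd - koffU and
## B = (kd/koffS - 1) konS koffU / konU  (smaller quadratic root, the
## branch with koffS <= kd < koffU)
.kdFromRates <- function(koffU, koffS, konS, konU, kUS) {
  g <- konS * koffU / (konU * koffS)
  c2 <- g
  c1 <- -g * (koffU + koffS + kUS) - kUS
  c0 <- g * koffS * (koffU + kUS) + kUS * koffU
  disc <- sqrt(max(c1^2 - 4 * c2 * c0, 0))
  (-c1 - disc) / (2 * c2)
}

## value-only solver used for the numeric error-propagation Jacobian
.tauSearchFromInputs <- function(pF, pU, pS, koffU, kd, ratio, konSStar) {
  koffS <- if (!is.na(ratio)) ratio * kd else konSStar * pF / pS
  r <- .solveRatesCore(pF, pU, pS, koffU, kd, koffS)
  .tauSearchFormula(r$konUStar, r$koffU, r$konSStar, r$kUS)
}

#' Solve the three-state model for all microscopic rates
#'
#' From measured fractions and effective dissociation rates plus one
#' closure, computes the direct specific dissociation rate, both
#' association rates, the microscopic u-s exchange rates (via detailed
#' balance), the effective specific association rate and the target-site
#' search time. Feasibility is policed, not clipped: the closure must
#' satisfy 0 < koffS <= kd and the inputs kd < koffU. If the input
#' carries standard deviations, the sd of the search time is propagated
#' by a first-order numeric Jacobian.
#'
#' Internally the solution is verified against the coarse-graining
#' decomposition of the effective dissociation rate,
#' \eqn{k_d = k_{off,s} + k_{s-u} k_{off,u} / (k_{off,u} + k_{u-s})},
#' and against the stationarity of the input fractions.
#'
#' @param input a [SearchModelInput-class]
#' @return a [SearchModelResult-class]
#' @examples
#' inp <- SearchModelInput(pF = 0.6, pU = 0.3, pS = 0.1,
#'                         koffU = 1, kd = 0.01, ratio = 0.5)
#' tauSearch(solveRates(inp))
#' @export
solveRates <- function(input) {
  stopifnot(is(input, "SearchModelInput"))
  koffS <- if (!is.na(input@ratio)) input@ratio * input@kd else
    input@konSStar * input@pF / input@pS
  if (koffS <= 0 || koffS > input@kd * (1 + 1e-12))
    stop("closure infeasible: need 0 < koffS <= kd (the direct specific ",
         "dissociation rate cannot exceed the effective one)")
  koffS <- min(koffS, input@kd)
  r <- .solveRatesCore(input@pF, input@pU, input@pS, input@koffU,
                       input@kd, koffS)
  rates <- ThreeStateRates(r$konUStar, r$koffU, r$konSStar, r$koffS,
                           r$kUS, r$kSU)
  tau <- .tauSearchFormula(r$konUStar, r$koffU, r$konSStar, r$kUS)
  # round-trip: inverting the u->s closure relation at the solved rates
  # must reproduce kd exactly
  if (r$kUS > 0) {
    kdBack <- .kdFromRates(r$koffU, r$koffS, r$konSStar, r$konUStar,
                           r$kUS)
    if (abs(kdBack - input@kd) / input@kd > 1e-9)
      stop("internal inconsistency: solved rates do not reproduce kd")
  }
  sdTau <- NA_real_
  if (all(is.finite(input@sds[c("pF", "pU", "pS", "koffU", "kd")]))) {
    x0 <- c(pF = input@pF, pU = input@pU, pS = input@pS,
            koffU = input@koffU, kd = input@kd)
    grad <- vapply(names(x0), function(nm) {
      h <- 1e-6 * x0[[nm]]
      xp <- x0; xp[[nm]] <- x0[[nm]] + h
      xm <- x0; xm[[nm]] <- x0[[nm]] - h
      # fractions are perturbed without renormalization: first-order only
      (.tauSearchFromInputs(xp[["pF"]], xp[["pU"]], xp[["pS"]],
                            xp[["koffU"]], xp[["kd"]], input@ratio,
                            input@konSStar) -
       .tauSearchFromInputs(xm[["pF"]], xm[["pU"]], xm[["pS"]],
                            xm[["koffU"]], xm[["kd"]], input@ratio,
                            input@konSStar)) / (2 * h)
    }, numeric(1))
    sdTau <- sqrt(sum((grad * input@sds[names(x0)])^2))
  }
  new("SearchModelResult", rates = rates, kAStar = 1 / tau,
      tauSearch = tau, sdTauSearch = sdTau,
      foldAcceleration = (1 / tau) / r$konSStar, input = input)
}

#' Target-site search time of a solved model
#'
#' Evaluates the closed-form mean first-passage time from the free to the
#' specific state; equal to the inverse effective specific association
#' rate.
#'
#' @param result a [SearchModelResult-class] or [ThreeStateRates-class]
#' @return search time in seconds
#' @export
searchTime <- function(result) {
  r <- if (is(result, "SearchModelResult")) result@rates else result
  stopifnot(is(r, "ThreeStateRates"))
  .tauSearchFormula(r@konUStar, r@koffU, r@konSStar, r@kUS)
}

#' Stationary distribution of a three-state rate set
#'
#' Null-space solution of the continuous-time generator over the states
#' (free, unspecific, specific); used to verify that solved rate sets are
#' consistent with the measured fractions.
#'
#' @param rates a [ThreeStateRates-class]
#' @return probabilities `c(pF, pU, pS)`
#' @export
stationaryDistribution <- function(rates) {
  stopifnot(is(rates, "ThreeStateRates"))
  Q <- matrix(c(
    -(rates@konUStar + rates@konSStar), rates@konUStar, rates@konSStar,
    rates@koffU, -(rates@koffU + rates@kUS), rates@kUS,
    rates@koffS, rates@kSU, -(rates@koffS + rates@kSU)),
    nrow = 3, byrow = TRUE)
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi <- qr.solve(A, b)
  setNames(pi, c("pF", "pU", "pS"))
}

#' Sweep the undetermined direct association rate
#'
#' Varies the closure rate konSStar over its feasible range (the upper
#' edge is konSStar = kd * pS / pF, where the direct pathway alone
#' carries all specific binding) and records the full solution at each
#' point. Infeasible points are marked, not fatal.
#'
#' @param input a [SearchModelInput-class] (its own closure is ignored)
#' @param decades number of orders of magnitude below the feasibility
#'   edge to span (default 3)
#' @param n number of sweep points
#' @return data.frame with columns konSStar, tauSearch, foldAcceleration,
#'   feasible; attributes `tauMin`/`tauMax` give the feasible extremes
#' @export
sweepKons <- function(input, decades = 3, n = 61L) {
  stopifnot(is(input, "SearchModelInput"))
  konsMax <- input@kd * input@pS / input@pF
  kons <- exp(seq(log(konsMax) - decades * log(10), log(konsMax),
                  length.out = n))
  rows <- lapply(kons, function(ks) {
    inp <- SearchModelInput(input@pF, input@pU, input@pS, input@koffU,
                            input@kd, konSStar = ks)
    res <- tryCatch(solveRates(inp), error = function(e) NULL)
    if (is.null(res))
      data.frame(konSStar = ks, tauSearch = NA_real_,
                 foldAcceleration = NA_real_, feasible = FALSE)
    else
      data.frame(konSStar = ks, tauSearch = res@tauSearch,
                 foldAcceleration = res@foldAcceleration, feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$feasible)) stop("no feasible point in the sweep range")
  attr(out, "tauMin") <- min(out$tauSearch[out$feasible])
  attr(out, "tauMax") <- max(out$tauSearch[out$feasible])
  out
}

#' Closure ratio for a given search acceleration
#'
#' Root-finds the ratio koffS/kd at which facilitated diffusion makes the
#' target-site search a given fold faster than direct specific
#' association alone, i.e. (1/konSStar) / tauSearch = fold. A useful
#' first-order approximation is r = pF / (fold * (1 - pS)).
#'
#' @param input a [SearchModelInput-class] (closure ignored)
#' @param fold desired acceleration factor (> 1)
#' @return the ratio in (0, 1)
#' @examples
#' inp <- SearchModelInput(0.6, 0.3, 0.1, koffU = 1, kd = 0.01)
#' solveRatioForAcceleration(inp, fold = 10)
#' @export
solveRatioForAcceleration <- function(input, fold = 10) {
  stopifnot(is(input, "SearchModelInput"))
  if (fold <= 1) stop("fold must be > 1")
  g <- function(r) {
    inp <- SearchModelInput(input@pF, input@pU, input@pS, input@koffU,
                            input@kd, ratio = r)
    res <- solveRates(inp)
    res@foldAcceleration - fold
  }
  lo <- 1e-8
  hi <- 1 - 1e-10
  flo <- tryCatch(g(lo), error = function(e) NA_real_)
  fhi <- tryCatch(g(hi), error = function(e) NA_real_)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no feasible ratio in (0, 1) achieves the requested acceleration")
  uniroot(g, c(lo, hi), tol = 1e-10)$root
}
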