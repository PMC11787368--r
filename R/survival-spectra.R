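## Dissociation-rate spectra from survival-time histograms.
##
## The observed survival probability of a track under a time-lapse
## condition with cycle time dt, for a binding class with dissociation
## rate k and per-frame bleaching number a, is
##     S(t) = exp(-k*t - a*t/dt)    at t = n*dt.
## A global fit couples all conditions through one shared amplitude vector
## over a fixed rate grid and one shared bleaching number; per-condition
## scale is fixed by normalizing at each condition's first evaluated time.
## With the model written as
##     S(t) = sum_l A_l e^(-kappa_l t) / sum_l A_l e^(-kappa_l t1)
## the misfit  S_obs(t) * sum_l A_l e^(-kappa_l t1) - sum_l A_l e^(-kappa_l t)
## is linear in A, so for a fixed bleaching number the amplitudes solve a
## non-negative least-squares problem; the bleaching number is then found
## by one-dimensional minimization of the weighted residual.

## Lawson-Hanson non-negative least squares on the normal equations.
## The fine log-spaced rate grid makes neighboring design columns nearly
## collinear; the active-set solves are therefore stabilized with a tiny
## diagonal jitter, which off-the-shelf NNLS implementations in this
## environment do not tolerate.
.nnls <- function(C, d, maxOuter = 10L * ncol(C)) {
  G <- crossprod(C)
  b <- drop(crossprod(C, d))
  n <- ncol(C)
  jit <- 1e-12 * mean(diag(G))
  solveP <- function(P) {
    p <- sum(P)
    drop(solve(G[P, P, drop = FALSE] + diag(jit, p), b[P]))
  }
  x <- numeric(n)
  P <- logical(n)
  w <- b
  tol <- 1e-10 * max(abs(b), 1)
  for (outer in seq_len(maxOuter)) {
    Z <- !P
    if (!any(Z) || max(w[Z]) <= tol) break
    im <- which(Z)[which.max(w[Z])]
    P[im] <- TRUE
    z <- numeric(n)
    z[P] <- solveP(P)
    inner <- 0L
    while (any(z[P] <= 0) && inner < 5L * n) {
      inner <- inner + 1L
      Q <- (z <= 0) & P
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      P <- P & (x > tol * 1e-3)
      z <- numeric(n)
      if (any(P)) z[P] <- solveP(P)
    }
    x <- z
    w <- b - drop(G %*% x)
  }
  pmax(x, 0)
}

#' Build a survival-time histogram
#'
#' Counts, for every multiple of the cycle time between the shortest and
#' longest observed duration, how many tracks lasted at least that long.
#'
#' @param durations observed track durations in seconds
#' @param condition the [TimeLapseCondition-class] the data come from
#' @return a [SurvivalHistogram-class]
#' @examples
#' cond <- TimeLapseCondition(0.1, minTrackFrames = 3)
#' h <- buildSurvivalHistogram(c(0.3, 0.5, 0.5, 0.9), cond)
#' h@counts
#' @export
buildSurvivalHistogram <- function(durations, condition) {
  stopifnot(is(condition, "TimeLapseCondition"))
  if (length(durations) == 0L) stop("no durations supplied")
  dt <- condition@cycleTime
  frames <- durations / dt
  off <- abs(frames - round(frames))
  if (any(off * dt > 1e-6)) {
    warning("durations are not multiples of the cycle time; snapping")
  }
  frames <- round(frames)
  if (any(frames < condition@minTrackFrames))
    stop("durations below the minimum track length for this condition")
  grid <- seq.int(min(frames), max(frames))
  counts <- vapply(grid, function(n) sum(frames >= n), numeric(1))
  new("SurvivalHistogram", condition = condition, times = grid * dt,
      counts = counts)
}

.defaultRateGrid <- function(spec = c(1e-4, 20, 200)) {
  exp(seq(log(spec[1]), log(spec[2]), length.out = spec[3]))
}

## Non-negative LS for the amplitudes at a fixed bleaching number.
##
## In the default "increments" mode the data rows are the per-frame
## event decrements d_n = counts_n - counts_(n+1) (with the events
## censored by the histogram end as the final row). Decrements of
## disjoint frame intervals are independent, whereas cumulative survival
## rows are strongly correlated -- a single long-lived track raises
## every row it survives through, which a least-squares fit would count
## as repeated independent evidence and convert into spurious ultra-slow
## spectral mass. The "survival" mode fits the cumulative rows directly.
##
## The per-condition normalization constants Z_j = sum_l A_l e^(-kappa_l
## t1_j) depend on the amplitudes themselves, so the constrained linear
## problem is solved by fixed-point iteration: hold Z_j at the previous
## iterate, solve the NNLS problem
##     min || sqrt(w) (y * Z_j - E A) ||^2  s.t. A >= 0, sum A = 1,
## recompute Z_j, repeat. The scale indeterminacy (A and Z can be scaled
## together) is resolved by renormalizing A to unit sum between
## iterations rather than by a penalty, so no amplitude can hide on grid
## rates that are already dark at the first evaluated time.
## Returns list(amps, rss): rss is the weighted residual of the
## normalized model over data rows.
.spectrumNnls <- function(prep, grid, a, ridge = 0, maxIter = 25L,
                          init = NULL) {
  L <- length(grid)
  blocks <- lapply(prep, function(p) {
    kappa <- grid + a / p$dt
    if (p$mode == "increments") {
      tNext <- c(p$t[-1], Inf)
      list(E1 = exp(-p$t1 * kappa),
           Et = exp(-outer(p$t, kappa)) - exp(-outer(tNext, kappa)),
           sw = sqrt(p$w), S = p$S)
    } else {
      list(E1 = exp(-p$t1 * kappa),               # length L
           Et = exp(-outer(p$t, kappa)),          # T x L
           sw = sqrt(p$w), S = p$S)
    }
  })
  rhs <- unlist(lapply(blocks, function(b) b$sw * b$S), use.names = FALSE)
  rhs <- c(rhs, numeric(L))
  rssOf <- function(A) {
    rss <- 0
    for (b in blocks) {
      Z <- sum(A * b$E1)
      model <- if (Z > 1e-300) drop(b$Et %*% A) / Z else
        rep(Inf, length(b$S))
      rss <- rss + sum(b$sw^2 * (b$S - model)^2)
    }
    rss
  }
  step <- function(A) {
    # each condition's design block is divided by its current
    # normalization constant so that every condition contributes at its
    # natural scale regardless of how much amplitude survives detection
    X <- do.call(rbind, lapply(blocks, function(b) {
      Z <- sum(A * b$E1)
      if (Z <= 1e-300) Z <- 1e-300
      b$Et * (b$sw / Z)
    }))
    # a tiny ridge block keeps the active-set solves full rank in the
    # face of near-collinear neighboring grid columns; it is far below
    # any data-driven scale and does not act as smoothing
    Xaug <- rbind(X, diag(sqrt(max(ridge, 1e-10)), L))
    newA <- .nnls(Xaug, rhs)
    if (sum(newA) <= 0) A else newA / sum(newA)
  }
  amps <- if (is.null(init)) rep(1 / L, L) else init
  prev <- NULL
  for (it in seq_len(maxIter)) {
    newA <- step(amps)
    delta <- max(abs(newA - amps))
    # the successive substitution is linearly convergent and can crawl;
    # an Aitken extrapolation every few iterations, accepted only when
    # it lowers the residual, cuts the tail of the iteration
    if (!is.null(prev) && it %% 4L == 0L && delta > 1e-12) {
      d1 <- amps - prev
      d2 <- newA - amps
      n1 <- sqrt(sum(d1^2))
      n2 <- sqrt(sum(d2^2))
      if (n1 > 0 && n2 < n1) {
        c <- n2 / n1
        extr <- pmax(newA + d2 * c / (1 - c), 0)
        if (sum(extr) > 0) {
          extr <- extr / sum(extr)
          if (rssOf(extr) < rssOf(newA)) newA <- extr
        }
      }
    }
    prev <- amps
    amps <- newA
    if (delta < 1e-12) break
  }
  list(amps = amps, rss = rssOf(amps))
}

#' Infer a dissociation-rate spectrum by inverse Laplace transformation
#'
#' Globally fits survival histograms from one or several time-lapse
#' conditions with a nonnegative amplitude distribution over a log-spaced
#' grid of dissociation rates plus a single per-frame bleaching number
#' shared by all conditions. With a single condition the bleaching number
#' is not identifiable and must be pinned via `bleach`.
#'
#' @param histograms list of [SurvivalHistogram-class] objects
#' @param rateGridSpec numeric `c(kMin, kMax, nPoints)`; default 200
#'   log-spaced points on [1e-4, 20] 1/s
#' @param bleach `NA` to fit the bleaching number, or a fixed value >= 0
#' @param weighting `"poisson"` (weights 1/max(counts, 1)) or `"uniform"`
#' @param fitMode `"increments"` (default) fits the statistically
#'   independent per-frame event decrements of each histogram;
#'   `"survival"` fits the cumulative survival rows directly, whose
#'   strong row-to-row correlation lets isolated long-lived tracks seed
#'   spurious ultra-slow spectral mass
#' @param ridge optional ridge penalty on the amplitudes (default 0)
#' @param bleachMax upper bound of the bleaching-number search
#' @param visibilityFloor classes whose probability of surviving to the
#'   first evaluated time is below this under every condition lie
#'   outside the observation bandwidth; their (unidentifiable) fitted
#'   amplitude is zeroed and the spectrum renormalized
#' @return a [DissociationSpectrum-class]
#' @examples
#' cond <- TimeLapseCondition(0.4)
#' tr <- GroundTruthSpectrum(rates = 0.5, weights = 1)
#' d <- simulateSurvivalData(tr, list(cond), nEvents = 2000, seed = 1)
#' s <- inferSpectrum(list(buildSurvivalHistogram(d[[1]], cond)),
#'                    bleach = 0)
#' rateGrid(s)[which.max(eventAmps(s))]
#' @export
inferSpectrum <- function(histograms, rateGridSpec = c(1e-4, 20, 200),
                          bleach = NA_real_, weighting = c("poisson",
                          "uniform"), fitMode = c("increments",
                          "survival"), ridge = 0, bleachMax = 0.5,
                          visibilityFloor = 0.01) {
  weighting <- match.arg(weighting)
  fitMode <- match.arg(fitMode)
  stopifnot(length(histograms) >= 1L,
            all(vapply(histograms, is, TRUE, "SurvivalHistogram")))
  nCycles <- length(unique(vapply(histograms,
                                  function(h) h@condition@cycleTime, 1)))
  if (is.na(bleach) && nCycles < 2L)
    stop("a single time-lapse condition cannot separate bleaching from ",
         "dissociation; pin the bleaching number via 'bleach'")
  total <- sum(vapply(histograms, function(h) h@counts[1], 1))
  if (total < 200)
    stop("too few events for spectrum inference (need >= 200)")
  grid <- .defaultRateGrid(rateGridSpec)
  prep <- lapply(histograms, function(h) {
    if (fitMode == "increments") {
      # deaths per frame interval; the final row carries the tracks
      # outliving the histogram end. The add-one in the Poisson weight
      # keeps zero-count rows finite and tempers the noise-correlation
      # of observed-count weights, which otherwise biases the shared
      # bleaching number upward
      d <- c(-diff(h@counts), h@counts[length(h@counts)])
      w <- if (weighting == "poisson") 1 / (d + 1) else rep(1, length(d))
      list(t1 = h@times[1], t = h@times, S = d / h@counts[1], w = w,
           dt = h@condition@cycleTime, mode = "increments")
    } else {
      S <- h@counts / h@counts[1]
      w <- if (weighting == "poisson") 1 / pmax(h@counts, 1) else
        rep(1, length(h@counts))
      keep <- -1L  # drop the first time: its residual is always zero
      list(t1 = h@times[1], t = h@times[keep], S = S[keep], w = w[keep],
           dt = h@condition@cycleTime, mode = "survival")
    }
  })
  if (!is.na(bleach)) {
    if (bleach < 0) stop("bleach must be >= 0")
    fit <- .spectrumNnls(prep, grid, bleach, ridge)
    aHat <- bleach
  } else {
    # coarse grid over the bleaching number, then local refinement
    # warm-started from the best coarse solution; the best fit seen
    # anywhere is kept (the amplitude solve can fall into a poorer
    # fixed point at isolated bleach values)
    best <- NULL
    bestA <- NA_real_
    consider <- function(a, init = NULL) {
      f <- .spectrumNnls(prep, grid, a, ridge, init = init)
      if (is.null(best) || f$rss < best$rss) {
        best <<- f
        bestA <<- a
      }
      f$rss
    }
    aGrid <- seq(0, bleachMax, length.out = 13)
    for (a in aGrid) consider(a)
    i <- match(bestA, aGrid)
    lo <- aGrid[max(1L, i - 1L)]
    hi <- aGrid[min(length(aGrid), i + 1L)]
    warm <- best$amps
    if (lo < hi)
      optimize(function(a) consider(a, init = warm), c(lo, hi),
               tol = 1e-3)
    fit <- best
    aHat <- bestA
  }
  if (sum(fit$amps) <= 0)
    stop("spectrum fit degenerated to the all-zero amplitude solution")
  amps <- fit$amps
  if (visibilityFloor > 0) {
    vis <- Reduce(pmax, lapply(prep, function(p)
      exp(-(grid + aHat / p$dt) * p$t1)))
    amps[vis < visibilityFloor] <- 0
  }
  if (sum(amps) <= 0)
    stop("no amplitude within the observation bandwidth")
  DissociationSpectrum(rateGrid = grid, eventAmps = amps,
                       bleachNumber = aHat, fitResidual = fit$rss)
}

#' Convert event amplitudes to state amplitudes
#'
#' State amplitudes weight each dissociation-rate class by snapshot
#' occupancy rather than by event frequency:
#' \eqn{A^s_l = (A^e_l / k_l) / \sum_m (A^e_m / k_m)}.
#'
#' @param eventAmps normalized event amplitudes
#' @param rateGrid dissociation rates (1/s), all > 0
#' @return state amplitudes summing to 1
#' @examples
#' eventToState(c(0.5, 0.5), c(1.0, 0.1))
#' @export
eventToState <- function(eventAmps, rateGrid) {
  if (any(rateGrid <= 0)) stop("rate grid must be strictly positive")
  if (abs(sum(eventAmps) - 1) > 1e-9)
    stop("event amplitudes must be normalized")
  st <- eventAmps / rateGrid
  st / sum(st)
}

#' Convert state amplitudes to event amplitudes
#'
#' Algebraic inverse of [eventToState()].
#'
#' @param stateAmps normalized state amplitudes
#' @param rateGrid dissociation rates (1/s)
#' @return event amplitudes summing to 1
#' @export
stateToEvent <- function(stateAmps, rateGrid) {
  if (any(rateGrid <= 0)) stop("rate grid must be strictly positive")
  if (abs(sum(stateAmps) - 1) > 1e-9)
    stop("state amplitudes must be normalized")
  ev <- stateAmps * rateGrid
  ev / sum(ev)
}

#' Resample-based uncertainty of the spectrum
#'
#' Repeats the spectrum inference on random subsets of the survival times
#' (by default 80 percent drawn without replacement per condition),
#' mirroring the standard resampling error estimate for inverse-Laplace
#' rate spectra.
#'
#' @param durations named list of raw durations per condition, as returned
#'   by [simulateSurvivalData()]
#' @param conditions matching list of [TimeLapseCondition-class] objects
#' @param nResamples number of resamples (default 500)
#' @param fraction fraction of survival times per resample, in (0, 1]
#' @param seed integer seed
#' @param ... passed on to [inferSpectrum()]
#' @return a [SpectrumResampleSet-class]
#' @export
resampleSpectra <- function(durations, conditions, nResamples = 500L,
                            fraction = 0.8, seed = 1L, ...) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  stopifnot(length(durations) == length(conditions))
  nResamples <- as.integer(nResamples)
  spectra <- vector("list", nResamples)
  for (r in seq_len(nResamples)) {
    set.seed(.splitSeed(seed, 5000 + r))
    hist <- lapply(seq_along(durations), function(j) {
      d <- durations[[j]]
      m <- max(1L, floor(fraction * length(d)))
      buildSurvivalHistogram(sample(d, m), conditions[[j]])
    })
    spectra[[r]] <- inferSpectrum(hist, ...)
  }
  new("SpectrumResampleSet", spectra = spectra,
      resampleFraction = fraction, nResamples = nResamples,
      seed = as.integer(seed))
}
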