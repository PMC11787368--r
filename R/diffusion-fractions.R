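## Jump-distance analysis of fast continuous movies: collect per-frame
## displacements (first jumps per track, gap jumps discarded) and fit the
## cumulative jump-distance distribution with a 2- or 3-component
## Brownian mixture,
##     P(r) = 1 - sum_i A_i exp(-r^2 / (4 D_i dt)),
## whose slowest-component amplitude is the overall bound fraction.
## Localization error is not a separate parameter; it is absorbed into
## the slowest diffusion coefficient.

#' Collect jump distances from a track table
#'
#' Keeps, per track, at most the first `maxJumpsPerTrack` displacements
#' between consecutive frames (avoiding overrepresentation of immobile
#' molecules, which produce long tracks); displacements spanning a missing
#' frame are discarded when `excludeGapJumps` is TRUE.
#'
#' @param tracks a [TrackTable-class]
#' @param frameInterval frame interval in seconds (defaults to the track
#'   table's)
#' @param maxJumpsPerTrack cap on jumps per track (default 5)
#' @param excludeGapJumps drop displacements across gap frames
#' @return a [JumpDataset-class]
#' @examples
#' tt <- TrackTable(data.frame(track_id = 1, frame = c(1, 2, 4, 5),
#'                             x_um = c(0, 1, 3, 4), y_um = 0),
#'                  frameInterval = 0.0117)
#' length(collectJumps(tt)@jumps)  # the gap jump 2 -> 4 is dropped
#' @export
collectJumps <- function(tracks, frameInterval = tracks@frameInterval,
                         maxJumpsPerTrack = 5L, excludeGapJumps = TRUE) {
  stopifnot(is(tracks, "TrackTable"))
  if (is.na(frameInterval) || frameInterval <= 0)
    stop("a positive frame interval is required")
  df <- tracks@tracks
  if (nrow(df) == 0L)
    return(new("JumpDataset", jumps = numeric(), frameInterval =
               as.numeric(frameInterval), firstJumpsOnly = TRUE,
               gapJumpsExcluded = excludeGapJumps))
  sameTrack <- df$track_id[-1L] == df$track_id[-nrow(df)]
  dFrame <- diff(df$frame)
  if (any(sameTrack & dFrame <= 0))
    stop("non-monotone frame indices within a track")
  dx <- diff(df$x_um)
  dy <- diff(df$y_um)
  ok <- sameTrack & (if (excludeGapJumps) dFrame == 1 else TRUE)
  jumpTrack <- df$track_id[-nrow(df)][ok]
  r <- sqrt(dx[ok]^2 + dy[ok]^2)
  if (is.finite(maxJumpsPerTrack)) {
    within <- ave(seq_along(jumpTrack), jumpTrack, FUN = seq_along)
    keep <- within <= maxJumpsPerTrack
    r <- r[keep]
  }
  new("JumpDataset", jumps = r, frameInterval = as.numeric(frameInterval),
      firstJumpsOnly = is.finite(maxJumpsPerTrack),
      gapJumpsExcluded = excludeGapJumps)
}

## Survival form of the mixture: 1 - CDF(r) = sum_i A_i exp(-r^2/(4 D_i dt)).
## For fixed D the amplitudes solve a nonnegative LS problem with the
## sum-to-one constraint appended as a weighted row.
.jumpAmps <- function(r2grid, ySurv, D, dt) {
  E <- exp(-r2grid %o% (1 / (4 * D * dt)))
  lam <- 10 * sqrt(length(ySurv))
  M <- rbind(E, rep(lam, length(D)))
  d <- c(ySurv, lam)
  A <- .nnls(M, d)
  if (sum(A) <= 0) return(list(A = rep(1 / length(D), length(D)),
                               rss = Inf))
  A <- A / sum(A)
  list(A = A, rss = sum((ySurv - drop(E %*% A))^2))
}

#' Fit a Brownian mixture to the cumulative jump-distance distribution
#'
#' The empirical cumulative distribution is evaluated on a 1 nm grid and
#' fitted in r-squared space with nonnegative fractions constrained to
#' sum to one. The fit is separable: diffusion coefficients are optimized
#' by Nelder-Mead over log D with multi-start initialization on
#' log-spaced grids, and the fractions solve a constrained linear
#' least-squares problem at each step. Ties between starts are broken by
#' lower residual, then by lower slow-component D.
#'
#' @param data a [JumpDataset-class]
#' @param nComponents number of diffusion components (1, 2 or 3)
#' @param gridStep evaluation grid step in um (default 1e-3 = 1 nm)
#' @return a [DiffusionFit-class]; the `degenerate` flag is set if two
#'   components collapsed within 5 percent in D
#' @export
fitCumulativeJumps <- function(data, nComponents = 3L, gridStep = 1e-3) {
  stopifnot(is(data, "JumpDataset"))
  nComponents <- as.integer(nComponents)
  if (!nComponents %in% 1:3)
    stop("nComponents must be 1, 2 or 3")
  if (length(data@jumps) < 10L) stop("too few jumps to fit")
  dt <- data@frameInterval
  rmax <- max(data@jumps)
  rgrid <- seq(gridStep, rmax, by = gridStep)
  F <- ecdf(data@jumps)
  ySurv <- 1 - F(rgrid)
  r2 <- rgrid^2
  obj <- function(logD) .jumpAmps(r2, ySurv, exp(logD), dt)$rss
  # multi-start on log-spaced D ladders plus a moments-based start
  Dmom <- mean(data@jumps^2) / (4 * dt)
  starts <- switch(nComponents,
    list(log(Dmom), log(Dmom / 5), log(Dmom * 2)),
    list(log(c(Dmom / 10, Dmom)), log(c(Dmom / 50, Dmom * 2)),
         log(c(0.05, 2))),
    list(log(c(Dmom / 50, Dmom / 5, Dmom)), log(c(0.02, 0.5, 5)),
         log(c(0.1, 1, 10)), log(c(Dmom / 100, Dmom / 10, Dmom * 2))))
  best <- NULL
  for (s0 in starts) {
    opt <- if (length(s0) == 1L)
      optimize(obj, c(s0 - 6, s0 + 4))
    else
      optim(s0, obj, method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-10))
    val <- if (length(s0) == 1L) opt$objective else opt$value
    par <- if (length(s0) == 1L) opt$minimum else opt$par
    cand <- list(par = par, val = val)
    if (is.null(best) || cand$val < best$val - 1e-14 ||
        (abs(cand$val - best$val) <= 1e-14 &&
         min(exp(cand$par)) < min(exp(best$par))))
      best <- cand
  }
  D <- exp(best$par)
  ord <- order(D)
  D <- D[ord]
  fit <- .jumpAmps(r2, ySurv, D, dt)
  degenerate <- nComponents > 1L && any(diff(D) / D[-length(D)] < 0.05)
  new("DiffusionFit", nComponents = nComponents, diffCoeffs = D,
      fractions = fit$A[ord], fB = fit$A[ord][1],
      sds = c(fB = NA_real_), residual = fit$rss,
      nJumps = length(data@jumps), degenerate = degenerate)
}

#' Choose between mixture fits by penalized residual
#'
#' Compares fits of different component numbers on the same data with a
#' Bayesian-type information criterion: `n * log(RSS / n) + p * log(n)`
#' with `n` the number of jumps and `p = 2 * nComponents - 1` free
#' parameters. Ties go to the model with fewer parameters.
#'
#' @param fit2,fit3 two [DiffusionFit-class] objects fitted to identical
#'   data (any component numbers)
#' @return the chosen fit, with attribute `"ic"` carrying both criteria
#' @export
selectModel <- function(fit2, fit3) {
  stopifnot(is(fit2, "DiffusionFit"), is(fit3, "DiffusionFit"))
  if (fit2@nJumps != fit3@nJumps)
    stop("fits were made on different data (jump counts differ)")
  n <- fit2@nJumps
  ic <- function(f) n * log(f@residual / n) + (2 * f@nComponents - 1) * log(n)
  ics <- c(ic(fit2), ic(fit3))
  pick <- if (abs(diff(ics)) < 1e-9) {
    if (fit2@nComponents <= fit3@nComponents) fit2 else fit3
  } else if (ics[1] < ics[2]) fit2 else fit3
  attr(pick, "ic") <- ics
  pick
}

#' Resampled uncertainty of the jump-distance fit
#'
#' Refits random subsets of the jumps (default 80 percent without
#' replacement) and reports the full-data fit with standard deviations of
#' the fractions and diffusion coefficients across resamples.
#'
#' @param data a [JumpDataset-class]
#' @param nComponents number of components
#' @param nResamples number of resamples (default 400)
#' @param fraction subset fraction in (0, 1]
#' @param seed integer seed
#' @return a [DiffusionFit-class] with populated `sds`
#' @export
resampleFit <- function(data, nComponents = 3L, nResamples = 400L,
                        fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  full <- fitCumulativeJumps(data, nComponents)
  mats <- matrix(NA_real_, nResamples, 2L * nComponents)
  for (r in seq_len(nResamples)) {
    set.seed(.splitSeed(seed, 9000 + r))
    m <- max(10L, floor(fraction * length(data@jumps)))
    sub <- new("JumpDataset", jumps = sample(data@jumps, m),
               frameInterval = data@frameInterval,
               firstJumpsOnly = data@firstJumpsOnly,
               gapJumpsExcluded = data@gapJumpsExcluded)
    f <- fitCumulativeJumps(sub, nComponents)
    mats[r, ] <- c(f@fractions, f@diffCoeffs)
  }
  sds <- apply(mats, 2, sd)
  names(sds) <- c(paste0("A", seq_len(nComponents)),
                  paste0("D", seq_len(nComponents)))
  sds <- c(sds, fB = unname(sds[1]))
  initialize(full, sds = sds)
}
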