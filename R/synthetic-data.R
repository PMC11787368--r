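## Synthetic measurement-process emulator. Every downstream stage of the
## package is testable against data from these generators, whose forward
## model mirrors the fitting model exactly: binding times are
## multi-exponential mixtures, photobleaching acts once per acquired frame,
## and tracks shorter than the per-condition minimum are censored away.

## All randomness flows from one integer seed; independent streams are
## derived with this splitter (kept below 2^31 - 1).
.splitSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 2011 + 7919 * offset) %%
    2147483629L
}

#' Standard set of time-lapse conditions
#'
#' Four time-lapse illumination schemes with 50 ms integration and frame
#' cycles of 0.1, 0.4, 1.6 and 6.4 s. Minimum track length is 3 frames for
#' the two fast cycles and 2 frames otherwise, with the matching gap-frame
#' allowances.
#'
#' @param movieCycles movie length in frame cycles per condition
#' @return list of [TimeLapseCondition-class] objects named by cycle time
#' @examples
#' names(standardConditions())
#' @export
standardConditions <- function(movieCycles = 3000) {
  cycles <- c(0.1, 0.4, 1.6, 6.4)
  minFrames <- c(3L, 3L, 2L, 2L)
  gaps <- c(2L, 1L, 1L, 1L)
  out <- lapply(seq_along(cycles), function(i)
    TimeLapseCondition(cycleTime = cycles[i], integrationTime = 0.05,
                       minTrackFrames = minFrames[i], maxGapFrames = gaps[i],
                       movieDuration = cycles[i] * movieCycles))
  names(out) <- sprintf("tl_%gs", cycles)
  out
}

#' Simulate survival-time data under time-lapse imaging
#'
#' Draws true binding durations from the exponential mixture in `truth`,
#' discretizes them into observed frames under each acquisition condition,
#' truncates each by an independent per-frame photobleaching lifetime, and
#' censors tracks shorter than the condition's minimum track length.
#' A binding event is visible only while the molecule is both bound and
#' fluorescent; bleaching acts per acquired frame (camera exposure), not
#' per unit time, which is what lets multiple frame-cycle times separate
#' bleaching from dissociation.
#'
#' @param truth a [GroundTruthSpectrum-class]
#' @param conditions list of [TimeLapseCondition-class] objects
#' @param nEvents number of binding events per condition: the number
#'   drawn (`count = "drawn"`) or the number surviving detection
#'   (`count = "observed"`, matching how movies are acquired until a
#'   target track count is reached)
#' @param seed integer seed
#' @param truncation `"discard"` drops events outlasting the movie;
#'   `"keep"` retains them at full length (movie-end truncation off)
#' @param count interpretation of `nEvents`, see above
#' @return named list (one element per condition) of observed track
#'   durations in seconds
#' @examples
#' tr <- GroundTruthSpectrum(rates = 0.5, weights = 1)
#' d <- simulateSurvivalData(tr, standardConditions()[1], nEvents = 100,
#'                           seed = 7)
#' head(d[[1]])
#' @export
simulateSurvivalData <- function(truth, conditions, nEvents, seed = 1L,
                                 truncation = c("discard", "keep"),
                                 count = c("drawn", "observed")) {
  stopifnot(is(truth, "GroundTruthSpectrum"))
  truncation <- match.arg(truncation)
  count <- match.arg(count)
  if (!is.numeric(nEvents) || nEvents < 1)
    stop("nEvents must be a positive count")
  if (length(conditions) == 0L)
    stop("at least one acquisition condition is required")
  if (truth@bleachNumber < 0) stop("bleachNumber must be >= 0")
  nEvents <- as.integer(nEvents)
  pBleach <- -expm1(-truth@bleachNumber)  # per-frame bleaching probability
  drawBatch <- function(cond, n) {
    comp <- sample.int(length(truth@rates), n, replace = TRUE,
                       prob = truth@eventWeights)
    tTrue <- rexp(n, rate = truth@rates[comp])
    nBind <- floor(tTrue / cond@cycleTime)
    nBright <- if (pBleach > 0) rgeom(n, prob = pBleach) else rep(Inf, n)
    nObs <- pmin(nBind, nBright)
    keep <- nObs >= cond@minTrackFrames
    if (truncation == "discard")
      keep <- keep & nObs <= floor(cond@movieDuration / cond@cycleTime)
    nObs[keep] * cond@cycleTime
  }
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    stopifnot(is(cond, "TimeLapseCondition"))
    set.seed(.splitSeed(seed, 100 + i))
    if (count == "drawn") {
      out[[i]] <- drawBatch(cond, nEvents)
    } else {
      # accumulate batches until nEvents tracks survive detection
      acc <- numeric(0)
      batch <- nEvents
      for (rep in 1:60) {
        acc <- c(acc, drawBatch(cond, batch))
        if (length(acc) >= nEvents) break
        frac <- max(length(acc) / (batch * rep), 1e-4)
        batch <- min(2e6, ceiling((nEvents - length(acc)) / frac * 1.2))
      }
      if (length(acc) < nEvents)
        warning("condition ", i, ": only ", length(acc),
                " of ", nEvents, " requested observed events generated")
      out[[i]] <- acc[seq_len(min(nEvents, length(acc)))]
    }
  }
  names(out) <- if (!is.null(names(conditions))) names(conditions) else
    vapply(conditions, function(cc) sprintf("tl_%gs", cc@cycleTime), "")
  out
}

#' Simulate fast-tracking jump-distance data
#'
#' Each track draws one diffusion component; true positions follow 2D
#' Brownian motion, and every localization carries independent Gaussian
#' error of the stated sigma per axis, so per-frame displacements have
#' per-axis variance 2*D*dt + 2*sigma^2. Track lengths (in localizations)
#' follow a geometric law with the configured mean, floored at 2.
#'
#' @param truth a [DiffusionGroundTruth-class]
#' @return a [TrackTable-class]
#' @examples
#' gt <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 1, locError = 0,
#'                            nTracks = 10L, seed = 3L)
#' trackData(simulateJumpData(gt))[1:4, ]
#' @export
simulateJumpData <- function(truth) {
  stopifnot(is(truth, "DiffusionGroundTruth"))
  n <- truth@nTracks
  if (n == 0L)
    return(TrackTable(frameInterval = truth@frameInterval))
  set.seed(.splitSeed(truth@seed, 1))
  comp <- sample.int(length(truth@fractions), n, replace = TRUE,
                     prob = truth@fractions)
  # geometric number of localizations with the given mean, at least 2
  lens <- 2L + rgeom(n, prob = 1 / (truth@meanTrackFrames - 1))
  total <- sum(lens)
  sdStep <- sqrt(2 * truth@diffCoeffs[comp] * truth@frameInterval)
  trackId <- rep.int(seq_len(n), lens)
  sdAll <- sdStep[trackId]
  isFirst <- !duplicated(trackId)
  dx <- rnorm(total, sd = sdAll)
  dy <- rnorm(total, sd = sdAll)
  # origin of each track replaces its first "step"
  dx[isFirst] <- runif(n, 0, 20)
  dy[isFirst] <- runif(n, 0, 20)
  x <- ave(dx, trackId, FUN = cumsum)
  y <- ave(dy, trackId, FUN = cumsum)
  if (truth@locError > 0) {
    x <- x + rnorm(total, sd = truth@locError)
    y <- y + rnorm(total, sd = truth@locError)
  }
  frame <- sequence(lens)
  TrackTable(data.frame(track_id = trackId, frame = frame,
                        x_um = x, y_um = y),
             frameInterval = truth@frameInterval)
}

#' Stochastic first-passage times of the three-state chain
#'
#' Exact simulation (exponential waiting times, categorical transitions)
#' of the chain free <-> unspecific <-> specific with the direct
#' free <-> specific edge, absorbing at the specific state. Used as the
#' independent oracle for the closed-form search time.
#'
#' @param rates a [ThreeStateRates-class]; only the rates leading toward
#'   absorption (konUStar, koffU, konSStar, kUS) matter
#' @param nWalkers number of independent walkers
#' @param seed integer seed
#' @return list with `mean`, `se` (seconds) and `n`
#' @examples
#' r <- ThreeStateRates(0, 1, 0.001, 0.005, 0, 0.005)
#' simulateThreeStateFpt(r, nWalkers = 200, seed = 2)$mean
#' @export
simulateThreeStateFpt <- function(rates, nWalkers, seed = 1L) {
  stopifnot(is(rates, "ThreeStateRates"))
  if (rates@konSStar == 0 && (rates@konUStar == 0 || rates@kUS == 0))
    stop("no path to the specific state: absorption impossible")
  if (rates@konUStar > 0 && rates@koffU == 0 && rates@kUS == 0)
    stop("unspecific state would be absorbing")
  nWalkers <- as.integer(nWalkers)
  set.seed(.splitSeed(seed, 42))
  outF <- rates@konUStar + rates@konSStar     # total exit rate from free
  outU <- rates@koffU + rates@kUS             # total exit rate from unspecific
  # vectorized over walkers: state 1 = free, 2 = unspecific; absorb at specific
  state <- rep(1L, nWalkers)
  tAcc <- numeric(nWalkers)
  active <- seq_len(nWalkers)
  while (length(active)) {
    inF <- state[active] == 1L
    rateOut <- ifelse(inF, outF, outU)
    tAcc[active] <- tAcc[active] + rexp(length(active), rate = rateOut)
    pToS <- ifelse(inF, rates@konSStar / outF, rates@kUS / outU)
    toS <- runif(length(active)) < pToS
    state[active[!toS]] <- ifelse(inF[!toS], 2L, 1L)
    active <- active[!toS]
  }
  list(mean = mean(tAcc), se = sd(tAcc) / sqrt(nWalkers), n = nWalkers)
}

#' Packaged wild-type-like ground truth
#'
#' A two-class dissociation spectrum whose state-weighted unspecific
#' residence time is 0.9 s (state weight 0.72) and specific residence time
#' 277 s (state weight 0.28), with per-frame bleaching number 0.04, paired
#' with a three-component diffusion ground truth whose slow fraction is
#' 0.37 (bound fraction), D = 0.05/0.8/4.0 um^2/s at 11.7 ms frames.
#'
#' @param nTracks number of fast-tracking tracks in the diffusion truth
#' @param seed seed stored in the diffusion truth
#' @return list with elements `spectrum` ([GroundTruthSpectrum-class]) and
#'   `diffusion` ([DiffusionGroundTruth-class])
#' @examples
#' wtPreset()$spectrum
#' @export
wtPreset <- function(nTracks = 4500L, seed = 1L) {
  spec <- GroundTruthSpectrum(rates = c(1 / 0.9, 1 / 277),
                              weights = c(0.72, 0.28),
                              bleachNumber = 0.04, weightType = "state")
  diff <- DiffusionGroundTruth(fractions = c(0.37, 0.33, 0.30),
                               diffCoeffs = c(0.05, 0.8, 4.0),
                               locError = 0.035, frameInterval = 0.0117,
                               meanTrackFrames = 20,
                               nTracks = nTracks, seed = seed)
  list(spectrum = spec, diffusion = diff)
}
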