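# shared fixtures for the suite

# toy three-state problem: fractions (0.6, 0.3, 0.1), koffU = 1 1/s,
# kd = 0.01 1/s, closure ratio 0.5; solved by hand from the flux-balance
# and detailed-balance relations
toyInput <- function(ratio = 0.5) {
  SearchModelInput(pF = 0.6, pU = 0.3, pS = 0.1, koffU = 1, kd = 0.01,
                   ratio = ratio)
}

# frozen hand-evaluated solution of the toy problem at ratio 0.5
toySolution <- list(koffS = 0.005, konSStar = 8.3333e-4,
                    konUStar = 0.5, kUS = 1.6695e-3, kSU = 5.0086e-3,
                    tauSearch = 899.5)

# noiseless survival histograms computed from the closed-form model
# S(t) = sum_l w_l exp(-k_l t - a t/dt), normalized per condition
noiselessHistograms <- function(rates, weights, a = 0,
                                conditions = standardConditions(),
                                maxFrames = 250, nEvents = 1e6) {
  lapply(conditions, function(cond) {
    dt <- cond@cycleTime
    n <- seq.int(cond@minTrackFrames, maxFrames)
    t <- n * dt
    S <- colSums(weights * exp(-outer(rates, t)))  # dissociation
    S <- S * exp(-a * n)                           # per-frame bleaching
    new("SurvivalHistogram", condition = cond, times = t,
        counts = nEvents * S / S[1])
  })
}

# random feasible three-state inputs for property tests
randomSearchInput <- function() {
  repeat {
    p <- runif(3, 0.08, 1)
    p <- p / sum(p)
    if (all(p > 0.05)) break
  }
  koffU <- runif(1, 0.5, 2)
  kd <- koffU * 10^-runif(1, 1.5, 3)
  SearchModelInput(pF = p[1], pU = p[2], pS = p[3], koffU = koffU,
                   kd = kd, ratio = runif(1, 0.05, 0.9))
}

# dominant-cluster location: state-amplitude-weighted mean rate within a
# multiplicative window around the heaviest grid point
clusterLocation <- function(spectrum, around, factor = 3) {
  g <- rateGrid(spectrum)
  w <- eventAmps(spectrum)
  sel <- g > around / factor & g < around * factor
  sum(w[sel] * g[sel]) / sum(w[sel])
}

gridStepFactor <- function(spec = c(1e-4, 20, 200)) {
  (spec[2] / spec[1])^(1 / (spec[3] - 1))
}
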