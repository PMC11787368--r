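# Survival, jump-distance and first-passage generators

test_that("simulated survival durations match the discretized-exponential mean", {
  k <- 0.5
  dt <- 0.1
  m <- 2L
  cond <- TimeLapseCondition(dt, minTrackFrames = m)
  tr <- GroundTruthSpectrum(rates = k, weights = 1, bleachNumber = 0)
  d <- simulateSurvivalData(tr, list(cond), nEvents = 50000, seed = 7)[[1]]
  # brute-force oracle: E[n * dt | n >= m] for n = floor(T/dt),
  # P(n = j) = q^j (1 - q), q = exp(-k dt)
  q <- exp(-k * dt)
  j <- m:5000
  pj <- q^j * (1 - q)
  muOracle <- sum(j * dt * pj) / sum(pj)
  sdOracle <- sqrt(sum((j * dt)^2 * pj) / sum(pj) - muOracle^2)
  expect_lt(abs(mean(d) - muOracle), 3 * sdOracle / sqrt(length(d)))
  # sanity: the left-censored discretized mean sits somewhat above the
  # continuous expectation 1/k = 2 s
  expect_lt(abs(muOracle - 2.0), 0.2)
})

test_that("survival generator is seed-deterministic with sane limiting cases", {
  cond <- TimeLapseCondition(0.4)
  tr <- GroundTruthSpectrum(rates = c(2, 0.02), weights = c(0.6, 0.4),
                            bleachNumber = 0.05)
  d1 <- simulateSurvivalData(tr, list(cond), 500, seed = 3)
  d2 <- simulateSurvivalData(tr, list(cond), 500, seed = 3)
  expect_identical(d1, d2)
  d3 <- simulateSurvivalData(tr, list(cond), 500, seed = 4)
  expect_false(identical(d1, d3))
  # overwhelming bleaching kills every track before the minimum length
  trB <- GroundTruthSpectrum(rates = 0.5, weights = 1, bleachNumber = 50)
  expect_length(simulateSurvivalData(trB, list(cond), 1000, seed = 1)[[1]], 0)
  expect_error(simulateSurvivalData(tr, list(cond), 0, seed = 1),
               "positive")
  expect_error(simulateSurvivalData(tr, list(), 10, seed = 1),
               "condition")
})

test_that("empirical survival converges to the exponential law (KS < 0.02)", {
  k <- 0.5
  dt <- 0.1
  cond <- TimeLapseCondition(dt, minTrackFrames = 2L)
  tr <- GroundTruthSpectrum(rates = k, weights = 1, bleachNumber = 0)
  d <- simulateSurvivalData(tr, list(cond), nEvents = 50000, seed = 21)[[1]]
  frames <- round(d / dt)
  m <- min(frames)
  grid <- m:max(frames)
  sEmp <- vapply(grid, function(n) mean(frames >= n), numeric(1))
  sTrue <- exp(-k * (grid - m) * dt)  # conditional on detection
  expect_lt(max(abs(sEmp - sTrue)), 0.02)
})

test_that("bleaching and dissociation commute in the generator", {
  # per-frame survival exp(-k dt - a) is the same whether the loss is
  # split between dissociation and bleaching or folded into the rate
  dt <- 0.4
  cond <- TimeLapseCondition(dt, minTrackFrames = 2L,
                             movieDuration = 10000)
  a <- 0.3
  k <- 0.5
  d1 <- simulateSurvivalData(
    GroundTruthSpectrum(rates = k, weights = 1, bleachNumber = a),
    list(cond), 20000, seed = 5)[[1]]
  d2 <- simulateSurvivalData(
    GroundTruthSpectrum(rates = k + a / dt, weights = 1,
                        bleachNumber = 0),
    list(cond), 20000, seed = 6)[[1]]
  frames1 <- round(d1 / dt)
  frames2 <- round(d2 / dt)
  hi <- max(quantile(frames1, 0.995), quantile(frames2, 0.995))
  breaks <- c(seq(1.5, hi) , Inf)
  t1 <- table(cut(frames1, breaks))
  t2 <- table(cut(frames2, breaks))
  keep <- (t1 + t2) > 10
  p <- suppressWarnings(chisq.test(rbind(t1[keep], t2[keep])))$p.value
  expect_gt(p, 0.01)
})

test_that("jump generator reproduces the Rayleigh law and the fractions", {
  gt <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 1, locError = 0,
                             frameInterval = 0.01, meanTrackFrames = 20,
                             nTracks = 6000L, seed = 9)
  jumps <- collectJumps(simulateJumpData(gt),
                        maxJumpsPerTrack = Inf)@jumps
  expect_gt(length(jumps), 1e5)
  pHat <- mean(jumps <= 0.2)
  pTrue <- 1 - exp(-0.2^2 / (4 * 1 * 0.01))  # Rayleigh CDF, = 1 - 1/e
  expect_equal(pTrue, 1 - exp(-1))
  se <- sqrt(pTrue * (1 - pTrue) / length(jumps))
  expect_lt(abs(pHat - pTrue), 3 * se)

  gt3 <- DiffusionGroundTruth(fractions = c(0.37, 0.33, 0.30),
                              diffCoeffs = c(0.05, 0.8, 4.0),
                              nTracks = 5000L, seed = 2)
  tt <- simulateJumpData(gt3)
  expect_identical(trackData(simulateJumpData(gt3)), trackData(tt))
  # slow-component share of tracks matches the multinomial draw: slow
  # tracks are identified by per-track mean squared jump (the slow and
  # intermediate components are ~6x apart in E[r^2], so with ~19 jumps
  # per track misclassification is negligible)
  df <- trackData(tt)
  r2 <- (ave(df$x_um, df$track_id, FUN = function(x) c(NA, diff(x))))^2 +
        (ave(df$y_um, df$track_id, FUN = function(x) c(NA, diff(x))))^2
  perTrack <- tapply(r2, df$track_id, mean, na.rm = TRUE)
  slowShare <- mean(perTrack < 0.0175)
  expect_lt(abs(slowShare - 0.37), 3 * sqrt(0.37 * 0.63 / 5000) + 0.01)

  empty <- simulateJumpData(DiffusionGroundTruth(1, 1, nTracks = 0L))
  expect_s4_class(empty, "TrackTable")
  expect_identical(nrow(trackData(empty)), 0L)
})

test_that("jump variance matches 2 D dt + 2 sigma^2 per axis", {
  sig <- 0.035
  D <- 0.05
  dt <- 0.0117
  gt <- DiffusionGroundTruth(fractions = 1, diffCoeffs = D,
                             locError = sig, frameInterval = dt,
                             nTracks = 4000L, seed = 13)
  jumps <- collectJumps(simulateJumpData(gt),
                        maxJumpsPerTrack = Inf)@jumps
  # E[r^2] = 4 D dt + 4 sigma^2 in 2D
  expect_equal(mean(jumps^2), 4 * D * dt + 4 * sig^2, tolerance = 0.03)
})

test_that("three-state first-passage simulation matches the closed form", {
  res <- solveRates(toyInput())
  g <- simulateThreeStateFpt(threeStateRates(res), nWalkers = 20000,
                             seed = 3)
  expect_lt(abs(g$mean - toySolution$tauSearch), 3 * g$se)
  # pure direct association is a single exponential
  pure <- ThreeStateRates(0, 0, 0.001, 0.005, 0, 0.005)
  g2 <- simulateThreeStateFpt(pure, nWalkers = 20000, seed = 4)
  expect_lt(abs(g2$mean - 1000), 3 * g2$se)
  g3 <- simulateThreeStateFpt(pure, nWalkers = 2000, seed = 8)
  g4 <- simulateThreeStateFpt(pure, nWalkers = 2000, seed = 8)
  expect_identical(g3, g4)
  # no path to absorption is rejected
  expect_error(simulateThreeStateFpt(
    ThreeStateRates(0.5, 1, 0, 0.01, 0, 0.01), 100, 1), "absorption")
})

test_that("wt preset encodes the calibrated residence times and slow fraction", {
  p <- wtPreset()
  ev <- p$spectrum@eventWeights
  rates <- p$spectrum@rates
  stateW <- (ev / rates) / sum(ev / rates)
  expect_equal(stateW, c(0.72, 0.28), tolerance = 1e-9)
  expect_equal(1 / rates[2], 277)
  expect_equal(1 / rates[1], 0.9)
  expect_equal(p$diffusion@fractions[1], 0.37)
  # file round trip
  f <- tempfile(fileext = ".json")
  writePreset(p, f)
  p2 <- readPreset(f)
  expect_equal(p2$spectrum@rates, p$spectrum@rates)
  expect_equal(p2$spectrum@eventWeights, p$spectrum@eventWeights)
  expect_equal(p2$diffusion@fractions, p$diffusion@fractions)
  expect_equal(p2$diffusion@diffCoeffs, p$diffusion@diffCoeffs)
})
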