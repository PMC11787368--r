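# Survival histograms and spectrum inference

test_that("survival histograms count tracks surviving to each grid time", {
  cond <- TimeLapseCondition(0.1, minTrackFrames = 3L)
  h <- buildSurvivalHistogram(c(0.3, 0.5, 0.5, 0.9), cond)
  at <- function(t) h@counts[match(TRUE, abs(h@times - t) < 1e-9)]
  expect_equal(c(at(0.3), at(0.5), at(0.9)), c(4, 3, 1))
  expect_equal(h@counts[1], 4)
  expect_true(all(diff(h@counts) <= 0))

  # all-equal durations give a single-point histogram
  h2 <- buildSurvivalHistogram(rep(0.5, 10), TimeLapseCondition(0.1,
    minTrackFrames = 2L))
  expect_length(h2@times, 1L)
  expect_equal(h2@counts, 10)

  expect_error(buildSurvivalHistogram(numeric(), cond), "no durations")
  expect_warning(buildSurvivalHistogram(c(0.31, 0.52, 0.5, 0.9), cond),
                 "snapping")
})

test_that("histogram of exponential draws matches the closed form", {
  cond <- TimeLapseCondition(0.1, minTrackFrames = 2L)
  tr <- GroundTruthSpectrum(rates = 0.5, weights = 1)
  d <- simulateSurvivalData(tr, list(cond), 50000, seed = 17)[[1]]
  h <- buildSurvivalHistogram(d, cond)
  sEmp <- h@counts / h@counts[1]
  sTrue <- exp(-0.5 * (h@times - h@times[1]))
  expect_lt(max(abs(sEmp - sTrue)), 0.02)
})

test_that("noiseless single-exponential data invert onto the correct rate", {
  hs <- noiselessHistograms(rates = 0.5, weights = 1)
  s <- inferSpectrum(hs, bleach = 0, weighting = "uniform",
                     fitMode = "survival")
  g <- rateGrid(s)
  step <- gridStepFactor()
  near <- g > 0.5 / step^1.5 & g < 0.5 * step^1.5
  expect_gte(sum(eventAmps(s)[near]), 0.95)
  # with the bleaching number left free it absorbs at most a whisker
  sFree <- inferSpectrum(hs, weighting = "uniform",
                         fitMode = "survival")
  expect_lt(bleachNumber(sFree), 0.01)
  expect_lt(abs(log(clusterLocation(sFree, 0.5) / 0.5)),
            1.5 * log(step))
})

test_that("per-frame bleaching is separated from dissociation", {
  a <- 0.05
  hs <- noiselessHistograms(rates = 0.5, weights = 1, a = a)
  s <- inferSpectrum(hs, weighting = "uniform", fitMode = "survival")
  expect_lt(abs(bleachNumber(s) - a) / a, 0.2)
  loc <- clusterLocation(s, around = 0.5)
  expect_lt(abs(log(loc / 0.5)), 1.5 * log(gridStepFactor()))
  # rate location is stable under doubled bleaching
  s2 <- inferSpectrum(noiselessHistograms(rates = 0.5, weights = 1,
                                          a = 2 * a),
                      weighting = "uniform", fitMode = "survival")
  loc2 <- clusterLocation(s2, around = 0.5)
  expect_lt(abs(log(loc2 / loc)), log(gridStepFactor()))
})

test_that("two well-separated rates split the event mass evenly", {
  hs <- noiselessHistograms(rates = c(5, 0.005), weights = c(0.5, 0.5),
                            maxFrames = 400)
  s <- inferSpectrum(hs, weighting = "uniform", fitMode = "survival")
  g <- rateGrid(s)
  mFast <- sum(eventAmps(s)[g > 0.5])
  mSlow <- sum(eventAmps(s)[g < 0.05])
  expect_lt(abs(mFast - 0.5), 0.05)
  expect_lt(abs(mSlow - 0.5), 0.05)
})

test_that("noiseless mixtures are recovered over random truths", {
  set.seed(42)
  step <- gridStepFactor()
  for (i in 1:20) {
    nR <- sample(2:3, 1)
    repeat {
      rates <- sort(10^runif(nR, -2.3, 0.7))
      if (nR == 1 || min(diff(log10(rates))) > 1) break
    }
    w <- runif(nR, 0.2, 1)
    w <- w / sum(w)
    hs <- noiselessHistograms(rates = rates, weights = w, maxFrames = 300)
    s <- inferSpectrum(hs, bleach = 0, weighting = "uniform",
                       fitMode = "survival")
    for (j in seq_len(nR)) {
      loc <- clusterLocation(s, around = rates[j])
      expect_lt(abs(log(loc / rates[j])), 1.5 * log(step))
    }
  }
})

test_that("fitted model survival is non-increasing for every condition", {
  p <- wtPreset()
  conds <- standardConditions()
  d <- simulateSurvivalData(p$spectrum, conds, 3000, seed = 2,
                            count = "observed")
  hs <- lapply(seq_along(d), function(i)
    buildSurvivalHistogram(d[[i]], conds[[i]]))
  s <- inferSpectrum(hs)
  for (cond in conds) {
    t <- cond@cycleTime * seq(cond@minTrackFrames, 200)
    kappa <- rateGrid(s) + bleachNumber(s) / cond@cycleTime
    model <- colSums(eventAmps(s) * exp(-outer(kappa, t)))
    expect_true(all(diff(model) <= 1e-12))
  }
})

test_that("single-condition inference demands a pinned bleach number", {
  cond <- TimeLapseCondition(0.4)
  tr <- GroundTruthSpectrum(rates = 0.5, weights = 1)
  d <- simulateSurvivalData(tr, list(cond), 2000, seed = 1)
  h <- list(buildSurvivalHistogram(d[[1]], cond))
  expect_error(inferSpectrum(h), "pin")
  expect_s4_class(inferSpectrum(h, bleach = 0), "DissociationSpectrum")
  expect_error(inferSpectrum(h, bleach = 0,
                             rateGridSpec = c(1e-4, 20, 50)), NA)
})

test_that("event and state amplitudes interconvert exactly", {
  expect_equal(eventToState(c(0.5, 0.5), c(1.0, 0.1)),
               c(0.0909, 0.9091), tolerance = 1e-3)
  expect_equal(eventToState(1, 2.5), 1)
  ev <- c(0.2, 0.5, 0.3)
  k <- c(5, 0.3, 0.004)
  expect_equal(stateToEvent(eventToState(ev, k), k), ev,
               tolerance = 1e-12)
  expect_error(eventToState(c(0.5, 0.5), c(0, 1)), "positive")
  expect_error(eventToState(c(0.5, 0.6), c(1, 1)), "normalized")
})

test_that("spectrum resampling is reproducible and degenerates correctly", {
  cond2 <- standardConditions()[c(1, 3)]
  tr <- GroundTruthSpectrum(rates = c(1, 0.005), weights = c(0.9, 0.1),
                            bleachNumber = 0.04)
  d <- simulateSurvivalData(tr, cond2, 1500, seed = 12,
                            count = "observed")
  hs <- lapply(seq_along(d), function(i)
    buildSurvivalHistogram(d[[i]], cond2[[i]]))
  full <- inferSpectrum(hs, bleach = 0.04)
  one <- resampleSpectra(d, cond2, nResamples = 1, fraction = 1,
                         seed = 5, bleach = 0.04)
  expect_equal(eventAmps(one@spectra[[1]]), eventAmps(full))
  rs1 <- resampleSpectra(d, cond2, nResamples = 3, fraction = 0.8,
                         seed = 5, bleach = 0.04)
  rs2 <- resampleSpectra(d, cond2, nResamples = 3, fraction = 0.8,
                         seed = 5, bleach = 0.04)
  expect_equal(lapply(rs1@spectra, eventAmps),
               lapply(rs2@spectra, eventAmps))
  expect_error(resampleSpectra(d, cond2, fraction = 1.2), "fraction")
})

test_that("normalization invariants hold on inferred spectra", {
  hs <- noiselessHistograms(rates = c(2, 0.01), weights = c(0.8, 0.2))
  s <- inferSpectrum(hs, bleach = 0, weighting = "uniform",
                     fitMode = "survival")
  expect_equal(sum(eventAmps(s)), 1, tolerance = 1e-9)
  expect_equal(sum(stateAmps(s)), 1, tolerance = 1e-9)
  st <- eventAmps(s) / rateGrid(s)
  expect_equal(stateAmps(s), st / sum(st), tolerance = 1e-9)
})
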