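# Jump collection and Brownian-mixture fitting

test_that("jump collection keeps first five consecutive-frame displacements", {
  mkTrack <- function(id, frames) data.frame(track_id = id,
    frame = frames, x_um = cumsum(rep(0.1, length(frames))), y_um = 0)
  tt <- TrackTable(rbind(mkTrack(1, 1:8), mkTrack(2, c(1, 2, 4, 5)),
                         mkTrack(3, 1:2)), frameInterval = 0.0117)
  j <- collectJumps(tt)
  # track 1: 7 consecutive jumps, first 5 kept; track 2: gap jump 2->4
  # dropped, 2 kept; track 3: 1 jump
  expect_length(j@jumps, 5L + 2L + 1L)
  expect_true(j@firstJumpsOnly)
  jAll <- collectJumps(tt, maxJumpsPerTrack = Inf,
                       excludeGapJumps = FALSE)
  expect_length(jAll@jumps, 7L + 3L + 1L)
  bad <- TrackTable(data.frame(track_id = 1, frame = c(1, 3, 2),
                               x_um = 0, y_um = 0),
                    frameInterval = 0.0117)
  expect_error(collectJumps(bad), "non-monotone")
})

test_that("single-component diffusion is recovered within 2 percent", {
  gt <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 1, locError = 0,
                             frameInterval = 0.01, nTracks = 4000L,
                             seed = 6)
  j <- collectJumps(simulateJumpData(gt), maxJumpsPerTrack = Inf)
  f <- fitCumulativeJumps(j, 1)
  expect_lt(abs(f@diffCoeffs - 1), 0.02)
  expect_equal(f@fractions, 1)
})

test_that("three-component truth yields the bound fraction within 0.03", {
  p <- wtPreset(nTracks = 4500L, seed = 5)
  j <- collectJumps(simulateJumpData(p$diffusion))
  expect_gt(length(j@jumps), 15000)
  f3 <- fitCumulativeJumps(j, 3)
  expect_lt(abs(boundFraction(f3) - 0.37), 0.03)
  expect_true(all(diff(diffCoeffs(f3)) > 0))
  expect_equal(sum(fractions(f3)), 1, tolerance = 1e-9)
  # the nested two-component model fits strictly worse
  f2 <- fitCumulativeJumps(j, 2)
  expect_gt(f2@residual, f3@residual)
  expect_identical(selectModel(f2, f3)@nComponents, 3L)
})

test_that("model selection penalizes parameters and rejects mixed data", {
  gt <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 0.8,
                             locError = 0, frameInterval = 0.0117,
                             nTracks = 2000L, seed = 8)
  j <- collectJumps(simulateJumpData(gt))
  f1 <- fitCumulativeJumps(j, 1)
  f2 <- fitCumulativeJumps(j, 2)
  # on genuine one-component data the richer model either collapses or
  # contributes a vanishing extra fraction, and is not selected
  expect_true(f2@degenerate || min(fractions(f2)) < 0.05 ||
              selectModel(f1, f2)@nComponents == 1L)
  # tie in residual goes to the fewer-parameter fit
  fTie <- initialize(f2, residual = f1@residual)
  expect_identical(selectModel(f1, fTie)@nComponents, 1L)
  jOther <- collectJumps(simulateJumpData(initialize(gt, seed = 9L,
                                                     nTracks = 1000L)))
  fOther <- fitCumulativeJumps(jOther, 2)
  expect_error(selectModel(f2, fOther), "different data")
})

test_that("random three-component truths are recovered within 0.05", {
  set.seed(11)
  for (i in 1:8) {
    A <- runif(3, 0.2, 1)
    A <- A / sum(A)
    D1 <- runif(1, 0.02, 0.1)
    Ds <- c(D1, D1 * runif(1, 5, 8), D1 * runif(1, 30, 60))
    gt <- DiffusionGroundTruth(fractions = A, diffCoeffs = Ds,
                               locError = 0, frameInterval = 0.0117,
                               nTracks = 4000L, seed = 100L + i)
    f <- fitCumulativeJumps(collectJumps(simulateJumpData(gt)), 3)
    expect_lt(max(abs(fractions(f) - A)), 0.05)
  }
})

test_that("dropping the first-jumps rule inflates the bound fraction", {
  # slow molecules produce much longer tracks here, so unrestricted jump
  # counting overrepresents them
  slow <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 0.05,
                               locError = 0, frameInterval = 0.0117,
                               meanTrackFrames = 40, nTracks = 1500L,
                               seed = 21)
  fast <- DiffusionGroundTruth(fractions = 1, diffCoeffs = 2,
                               locError = 0, frameInterval = 0.0117,
                               meanTrackFrames = 5, nTracks = 3500L,
                               seed = 22)
  dfS <- trackData(simulateJumpData(slow))
  dfF <- trackData(simulateJumpData(fast))
  dfF$track_id <- dfF$track_id + max(dfS$track_id)
  tt <- TrackTable(rbind(dfS, dfF), frameInterval = 0.0117)
  fFirst <- fitCumulativeJumps(collectJumps(tt), 2)
  fAll <- fitCumulativeJumps(collectJumps(tt, maxJumpsPerTrack = Inf), 2)
  expect_gt(boundFraction(fAll), boundFraction(fFirst))
})

test_that("jump-fit resampling is reproducible and trivially consistent", {
  p <- wtPreset(nTracks = 1200L, seed = 3)
  j <- collectJumps(simulateJumpData(p$diffusion))
  full <- fitCumulativeJumps(j, 3)
  one <- resampleFit(j, 3, nResamples = 1, fraction = 1, seed = 2)
  expect_equal(fractions(one), fractions(full), tolerance = 1e-9)
  expect_equal(diffCoeffs(one), diffCoeffs(full), tolerance = 1e-9)
  rs1 <- resampleFit(j, 3, nResamples = 5, fraction = 0.8, seed = 4)
  rs2 <- resampleFit(j, 3, nResamples = 5, fraction = 0.8, seed = 4)
  expect_equal(rs1@sds, rs2@sds)
  expect_gt(rs1@sds[["fB"]], 0)
  expect_lt(rs1@sds[["fB"]], 0.05)
  expect_error(resampleFit(j, 3, fraction = 0), "fraction")
})
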