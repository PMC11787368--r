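# Three-state facilitated-diffusion solver

test_that("the unspecific association rate follows from flux balance", {
  expect_equal(unspecificOnRate(0.3, 0.6, 1.0), 0.5)
  expect_equal(unspecificOnRate(0, 0.6, 1.0), 0)
  expect_equal(unspecificOnRate(0.272, 0.63, 1 / 0.9), 0.4797,
               tolerance = 1e-4)
  expect_error(unspecificOnRate(0.3, 0, 1), "pF")
})

test_that("the toy problem solves to the hand-derived rates and search time", {
  res <- solveRates(toyInput())
  r <- threeStateRates(res)
  expect_equal(r@koffS, toySolution$koffS, tolerance = 1e-9)
  expect_equal(r@konSStar, toySolution$konSStar, tolerance = 1e-4)
  expect_equal(r@konUStar, toySolution$konUStar, tolerance = 1e-12)
  expect_equal(r@kUS, toySolution$kUS, tolerance = 1e-4)
  expect_equal(r@kSU, toySolution$kSU, tolerance = 1e-4)
  expect_equal(tauSearch(res), toySolution$tauSearch, tolerance = 1e-4)
  expect_equal(searchTime(res), tauSearch(res))
  expect_equal(1 / res@kAStar, tauSearch(res))
  # two-state coarse-graining decomposition of the effective
  # dissociation rate holds to 0.1 percent when kd << koffU
  kdBack <- r@koffS + r@kSU * r@koffU / (r@koffU + r@kUS)
  expect_lt(abs(kdBack - 0.01) / 0.01, 1e-3)
  # near-invariance of the search time in the closure
  res9 <- solveRates(toyInput(ratio = 0.9))
  expect_equal(tauSearch(res9), 900.0, tolerance = 1e-3)
})

test_that("the degenerate closure koffS = kd has a pure direct pathway", {
  res <- solveRates(toyInput(ratio = 1))
  r <- threeStateRates(res)
  expect_equal(r@kUS, 0)
  expect_equal(r@kSU, 0)
  expect_equal(tauSearch(res),
               (r@konUStar + r@koffU) / (r@konSStar * r@koffU))
  # with no unspecific binding at all, search is a single exponential
  pure <- ThreeStateRates(0, 1, 0.001, 0.005, 0, 0.005)
  expect_equal(searchTime(pure), 1 / 0.001)
})

test_that("infeasible inputs are rejected with explanations", {
  expect_error(SearchModelInput(0.6, 0.3, 0.1, koffU = 0.01, kd = 1),
               "kd must be smaller")
  expect_error(SearchModelInput(0.6, 0.3, 0.1, koffU = 1, kd = 0.01,
                                ratio = 1.5), "\\(0, 1\\]")
  # konSStar closure implying koffS > kd is infeasible
  inp <- SearchModelInput(0.6, 0.3, 0.1, koffU = 1, kd = 0.01,
                          konSStar = 0.01)
  expect_error(solveRates(inp), "infeasible")
})

test_that("detailed balance and stationarity hold for solved models", {
  set.seed(19)
  for (i in 1:20) {
    inp <- randomSearchInput()
    res <- solveRates(inp)
    r <- threeStateRates(res)
    lhs <- (r@konUStar / r@koffU) * (r@kUS / r@kSU)
    rhs <- r@konSStar / r@koffS
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
    pi <- stationaryDistribution(r)
    expect_lt(max(abs(pi - c(inp@pF, inp@pU, inp@pS))), 1e-6)
    # inverting the u->s closure relation recovers kd exactly
    kdBack <- TrackKinetics:::.kdFromRates(r@koffU, r@koffS, r@konSStar,
                                           r@konUStar, r@kUS)
    expect_lt(abs(kdBack - inp@kd) / inp@kd, 1e-9)
  }
})

test_that("stochastic first passage matches the closed form over random models", {
  set.seed(23)
  for (i in 1:20) {
    inp <- randomSearchInput()
    res <- solveRates(inp)
    g <- simulateThreeStateFpt(threeStateRates(res), nWalkers = 3000,
                               seed = 400 + i)
    expect_lt(abs(g$mean - tauSearch(res)), 3 * g$se)
  }
})

test_that("the search time is nearly invariant over the closure sweep", {
  sw <- sweepKons(toyInput(), decades = 3, n = 61)
  expect_true(all(sw$feasible))
  expect_lt(attr(sw, "tauMax") / attr(sw, "tauMin") - 1, 0.002)
  # fold acceleration decreases as direct association strengthens
  expect_true(all(diff(sw$foldAcceleration) < 0))
  # at the feasibility edge the whole search runs through the direct
  # pathway (with unspecific excursions)
  edge <- sw[nrow(sw), ]
  konsMax <- 0.01 * 0.1 / 0.6
  expect_equal(edge$konSStar, konsMax, tolerance = 1e-9)
  expect_equal(edge$tauSearch, (1 + 0.3 / 0.6) / konsMax,
               tolerance = 1e-6)
})

test_that("the closure ratio for a tenfold acceleration is recovered", {
  r10 <- solveRatioForAcceleration(toyInput(), fold = 10)
  expect_equal(r10, 0.0667, tolerance = 0.0005 / 0.0667)
  # closed-form approximation r = pF / (fold (1 - pS)), exact up to the
  # sub-percent variation of the search time over the closure range
  expect_equal(r10, 0.6 / (10 * 0.9), tolerance = 5e-3)
  # fractions like the wild-type measurement give the conventional 0.0705
  inp <- SearchModelInput(0.636, 0.266, 0.098, koffU = 1 / 0.9,
                          kd = 1 / 247)
  expect_equal(solveRatioForAcceleration(inp, fold = 10), 0.0705,
               tolerance = 1e-3)
  expect_error(solveRatioForAcceleration(toyInput(), fold = 0.5),
               "fold")
})

test_that("the effective-rate identity links search and residence times", {
  for (ratio in c(0.05, 0.3, 0.7, 1)) {
    res <- solveRates(toyInput(ratio = ratio))
    tauS <- 1 / res@input@kd
    expect_equal(tauSearch(res) * res@input@pS / (1 - res@input@pS),
                 tauS, tolerance = 0.01)
  }
})

test_that("input uncertainties propagate to the search time", {
  inp <- SearchModelInput(0.6, 0.3, 0.1, koffU = 1, kd = 0.01,
                          ratio = 0.5,
                          sds = c(pF = 0.02, pU = 0.015, pS = 0.008,
                                  koffU = 0.05, kd = 0.0008))
  res <- solveRates(inp)
  expect_gt(res@sdTauSearch, 0)
  # first-order propagation is linear in the input sds
  inpHalf <- initialize(inp, sds = inp@sds / 2)
  expect_equal(solveRates(inpHalf)@sdTauSearch, res@sdTauSearch / 2,
               tolerance = 1e-6)
})
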