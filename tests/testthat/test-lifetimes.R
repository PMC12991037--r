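test_that("trace binning counts events and drops the partial tail bin", {
  st <- PhotonStream("m", seq(0, 0.045, by = 0.005), rep(1, 10), 25)
  tr <- binTrace(st, 0.01)
  expect_equal(binCounts(tr), rep(2, 4))
  expect_equal(sum(binCounts(tr)), 8)   # last partial bin dropped

  expect_warning(tr0 <- binTrace(PhotonStream("m", numeric(0), numeric(0), 25),
                                 0.01), "empty")
  expect_equal(sum(binCounts(tr0)), 0)

  # Poisson stream: mean counts per bin ~ rate * binWidth
  sim <- simulatePhotonStream(trueTau = 1, brightness = 0, backgroundRate = 5e3,
                              bleachRate = 0, duration = 4, seed = 1)
  tr <- binTrace(sim$stream, 0.01)
  expect_lt(abs(mean(binCounts(tr)) - 50), 4 * sqrt(50 / length(binCounts(tr))))

  # bin wider than the stream: the drop rule leaves a single covering bin
  trWide <- binTrace(st, 1)
  expect_equal(sum(binCounts(trWide)), 10)
})

test_that("change-point detection finds single steps and rejects two-dye traces", {
  set.seed(10)
  # constant-rate trace: no change points
  flat <- pieceTrace(100, 300)
  expect_length(detectBleachSteps(flat), 0)

  # 300 -> 30 step at bin 150: localized within +/- 2 bins in >= 95% of reps
  hits <- 0L
  for (i in 1:200) {
    tr <- pieceTrace(c(300, 30), c(150, 150))
    cps <- detectBleachSteps(tr)
    if (length(cps) == 1L && abs(cps - 150) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)

  # two sequential bleach steps: n_steps = 2, molecule would be rejected
  tr2 <- pieceTrace(c(400, 200, 2), c(100, 100, 100))
  cls <- classifyBleachSteps(tr2, detectBleachSteps(tr2), background = 2)
  expect_identical(cls$nSteps, 2L)

  # single step to background: n_steps = 1, bleach time at the step
  tr1 <- pieceTrace(c(200, 2), c(150, 150))
  cls1 <- classifyBleachSteps(tr1, detectBleachSteps(tr1), background = 2)
  expect_identical(cls1$nSteps, 1L)
  expect_equal(cls1$bleachTime, 1.5, tolerance = 0.03)
})

test_that("decay histograms respect the bleach cut and the delay moment", {
  sim <- simulatePhotonStream(trueTau = 1, irfSigma = 0.1, brightness = 5e3,
                              backgroundRate = 100, bleachRate = 0,
                              duration = 10, seed = 3)
  st <- sim$stream
  dOn <- buildDecay(st, bleachTime = 5, postBleachExclusion = TRUE)
  dOff <- buildDecay(st, bleachTime = 5, postBleachExclusion = FALSE)
  expect_equal(sum(dOn@counts), sum(macroTime(st) < 5))
  expect_equal(sum(dOff@counts), length(macroTime(st)))

  # noiseless decay: mean delay = IRF offset + tau
  simc <- simulatePhotonStream(trueTau = 1, irfSigma = 0.05, brightness = 5e4,
                               backgroundRate = 0, bleachRate = 0, duration = 1,
                               irfOffset = 2, seed = 4)
  dec <- buildDecay(simc$stream, postBleachExclusion = FALSE)
  mids <- (dec@binEdges[-1] + dec@binEdges[-length(dec@binEdges)]) / 2
  meanDelay <- sum(mids * dec@counts) / sum(dec@counts)
  expect_lt(abs(meanDelay - 3), 0.02)

  expect_error(buildDecay(st, nBins = 16), "nBins")
})

test_that("the reconvolution MLE recovers lifetimes without bias", {
  dec <- simulateDecay(3.5, nPhotons = 5e4, bgFraction = 0.02, seed = 5)
  fit <- fitMonoexponential(dec)
  expect_true(isConverged(fit))
  expect_lt(abs(lifetime(fit) - 3.5), 3 * lifetimeSe(fit))

  # small bias over repeated fits
  errs <- vapply(1:20, function(i) {
    f <- fitMonoexponential(simulateDecay(3.5, nPhotons = 5e4, seed = 100 + i))
    lifetime(f) - 3.5
  }, numeric(1))
  expect_lt(abs(mean(errs)) / 3.5, 0.01)
})

test_that("a background-only decay is declared unidentifiable", {
  sim <- simulatePhotonStream(trueTau = 1, brightness = 0, backgroundRate = 5e3,
                              bleachRate = 0, duration = 1, seed = 6)
  dec <- buildDecay(sim$stream, postBleachExclusion = FALSE)
  fit <- fitMonoexponential(dec)
  expect_false(isConverged(fit))
})

test_that("with no IRF the fit matches the closed-form exponential MLE", {
  # sharp-edge decay at zero offset, no background, unwrapped
  sim <- simulatePhotonStream(trueTau = 2, irfSigma = 0, brightness = 2e5,
                              backgroundRate = 0, bleachRate = 0, duration = 1,
                              excitationPeriod = 200, irfOffset = 0, seed = 7)
  dec <- buildDecay(sim$stream, nBins = 2048L, postBleachExclusion = FALSE)
  fit <- fitMonoexponential(dec, irfSigma = 0)
  closedForm <- mean(microTime(sim$stream)) - fit@t0
  expect_lt(abs(lifetime(fit) - closedForm), 1e-3)
})

test_that("MLE and LSQ agree on high-count decays", {
  dec <- simulateDecay(2, nPhotons = 1e5, seed = 8)
  fm <- fitMonoexponential(dec, fitMode = "mle")
  fl <- fitMonoexponential(dec, fitMode = "lsq")
  expect_lt(abs(lifetime(fm) - lifetime(fl)) / lifetime(fm), 0.03)
})

test_that("raising the photon threshold never accepts more molecules", {
  pops <- data.frame(mean_tau = 2.5, sd_tau = 0.15, weight = 1)
  coh <- simulateCohort(pops, 25, photonParams = brightPhotonParams(), seed = 9)
  acc <- vapply(c(100, 2000, 2e4, 2e5), function(mp)
    sum(fitLifetimes(coh$streams, minPhotons = mp, background = 2)$accepted),
    numeric(1))
  expect_true(all(diff(acc) <= 0))
})
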