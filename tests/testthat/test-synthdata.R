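test_that("photon streams satisfy their invariants and bleaching removes signal", {
  sim <- simulatePhotonStream(trueTau = 3.5, irfSigma = 0.1, brightness = 2e4,
                              backgroundRate = 200, bleachRate = 0.2,
                              duration = 30, seed = 1)
  st <- sim$stream
  expect_true(!is.unsorted(macroTime(st)))
  expect_true(all(microTime(st) >= 0 & microTime(st) < tcspcWindow(st)))

  # post-bleach the only source is background: segment rate ~ 200 counts/s
  tb <- sim$truth$bleach_time_s
  expect_lt(tb, 30)
  post <- sum(macroTime(st) > tb)
  expectPost <- 200 * (30 - tb)
  expect_lt(abs(post - expectPost), 4 * sqrt(expectPost))

  # pre-bleach rate is brightness + background
  pre <- sum(macroTime(st) <= tb)
  expectPre <- (2e4 + 200) * tb
  expect_lt(abs(pre - expectPre), 4 * sqrt(expectPre))
})

test_that("a sourceless stream is empty and invalid parameters are named", {
  sim <- simulatePhotonStream(trueTau = 1, brightness = 0, backgroundRate = 0,
                              duration = 1, seed = 1)
  expect_identical(nPhotons(sim$stream), 0L)
  expect_error(simulatePhotonStream(trueTau = -1, brightness = 1, duration = 1),
               "trueTau")
  expect_error(simulatePhotonStream(trueTau = 1, brightness = 1, duration = 0),
               "duration")
})

test_that("with no IRF and no background the delay mean recovers the lifetime", {
  # unwrapped regime: period far exceeds any delay, offset zero, so the
  # closed-form exponential MLE is just the mean micro-time
  sim <- simulatePhotonStream(trueTau = 3, irfSigma = 0, brightness = 2e4,
                              backgroundRate = 0, bleachRate = 0, duration = 10,
                              excitationPeriod = 1000, irfOffset = 0, seed = 2)
  n <- nPhotons(sim$stream)
  expect_gt(n, 1e5)
  tauHat <- mean(microTime(sim$stream))
  expect_lt(abs(tauHat - 3), 4 * 3 / sqrt(n))
})

test_that("cohort component fractions follow the binomial sampling bound", {
  pops <- data.frame(mean_tau = c(1.0, 3.5), sd_tau = 0.15, weight = c(0.5, 0.5))
  coh <- simulateCohort(pops, 400, photonParams = cheapPhotonParams(), seed = 7)
  frac <- mean(coh$truth$population == "pop1")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
  expect_true(all(coh$truth$true_tau_ns > 0.05))
})

test_that("cohort weights are normalization-invariant and seeds reproduce", {
  p1 <- data.frame(mean_tau = c(1, 3.5), sd_tau = 0.1, weight = c(2, 2))
  p2 <- data.frame(mean_tau = c(1, 3.5), sd_tau = 0.1, weight = c(1, 1))
  a <- simulateCohort(p1, 30, photonParams = cheapPhotonParams(), seed = 3)
  b <- simulateCohort(p2, 30, photonParams = cheapPhotonParams(), seed = 3)
  expect_identical(a$truth, b$truth)
  expect_identical(macroTime(a$streams[[5]]), macroTime(b$streams[[5]]))
  expect_error(simulateCohort(data.frame(), 10), "non-empty")
})

test_that("the geometric forward model reproduces the deterministic chain", {
  # perpendicular duplex: d = n_bp * rise + linker
  gt <- geometryForwardModel(nBp = 12, rise = 0.34, linkerOffset = 1.1,
                             tiltMean = 90, tiltSd = 0, nMolecules = 3, seed = 1)
  expect_equal(gt$true_distance_nm, rep(12 * 0.34 + 1.1, 3), tolerance = 1e-12)
  expect_equal(unique(gt$true_distance_nm), 5.18)

  # at d = d0 the lifetime is half the unquenched value
  gt2 <- geometryForwardModel(nBp = 12, linkerOffset = 7.4 - 12 * 0.34,
                              tiltMean = 90, tiltSd = 0, d0 = 7.4,
                              tau0 = 3.5, nMolecules = 1, seed = 1)
  expect_equal(gt2$true_tau_ns, 1.75, tolerance = 1e-12)

  # tilt spread only lowers the mean height (concavity of sin)
  gt3 <- geometryForwardModel(nBp = 12, tiltMean = 90, tiltSd = 10,
                              nMolecules = 1e4, seed = 4)
  expect_lt(mean(gt3$true_distance_nm), 5.18)
  expect_error(geometryForwardModel(nBp = 12, d0 = -1, nMolecules = 1), "d0")
})

test_that("simulated trajectories place the tip by the sine law", {
  tj <- simulateTrajectory(nBp = 12, nFrames = 3, tiltMean = 90, tiltSd = 0,
                           seed = 1)
  g <- analyzeTrajectory(tj)
  expect_equal(tipDistanceSeries(g), rep(12 * 0.34, 3), tolerance = 1e-9)

  # degenerate rod along the axis stays on the surface
  tj0 <- simulateTrajectory(nBp = 12, nFrames = 2, tiltMean = 1e-6,
                            tiltSd = 0, seed = 1)
  g0 <- analyzeTrajectory(tj0)
  expect_lt(max(tipDistanceSeries(g0)), 0.2)

  # determinism
  a <- simulateTrajectory(nBp = 15, nFrames = 4, tiltMean = 80, tiltSd = 15,
                          seed = 9)
  b <- simulateTrajectory(nBp = 15, nFrames = 4, tiltMean = 80, tiltSd = 15,
                          seed = 9)
  expect_identical(a@frames, b@frames)
})

test_that("toy spectra are normalized and peak overlap occurs at zero shift", {
  grid <- seq(400, 800, by = 0.5)
  sp <- makeToySpectra(550, 30, 550, 30, grid = grid)
  em <- sp$emission
  area <- sum(diff(em$wavelength_nm) *
                (em$value[-1] + em$value[-nrow(em)]) / 2)
  expect_equal(area, 1, tolerance = 1e-9)

  j0 <- overlapIntegral(sp$emission, sp$absorption)
  for (shift in c(-40, -20, -10, 10, 20, 40)) {
    sps <- makeToySpectra(550, 30, 550 + shift, 30, grid = grid)
    expect_lt(overlapIntegral(sps$emission, sps$absorption), j0)
  }

  # disjoint bands overlap to (numerically) nothing
  spd <- suppressWarnings(makeToySpectra(450, 10, 750, 10, grid = grid))
  jd <- overlapIntegral(spd$emission, spd$absorption)
  expect_lt(jd / j0, 1e-10)

  expect_warning(makeToySpectra(550, 30, 1150, 30, grid = seq(400, 1200, 2)),
                 "3 FWHM")
})
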