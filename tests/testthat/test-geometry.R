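test_that("trajectories round-trip through XYZ + group map files", {
  tj <- simulateTrajectory(nBp = 12, nFrames = 3, tiltMean = 75, tiltSd = 5,
                           seed = 2)
  xyz <- tempfile(fileext = ".xyz"); grp <- tempfile(fileext = ".csv")
  writeTrajectory(tj, xyz, grp)
  back <- readTrajectory(xyz, grp)
  expect_identical(nFrames(back), 3L)
  for (f in 1:3)
    expect_lt(max(abs(frameCoords(back, f) - frameCoords(tj, f))), 1e-6)
  expect_identical(groupMap(back)$group, groupMap(tj)$group)

  # group map without the tip flag column is rejected
  g2 <- groupMap(tj); g2$tip <- NULL
  grp2 <- tempfile(fileext = ".csv")
  utils::write.csv(g2, grp2, row.names = FALSE)
  expect_error(readTrajectory(xyz, grp2), "tip")

  # truncated frame block is rejected with the frame named
  lines <- readLines(xyz)
  writeLines(lines[1:(length(lines) - 2)], xyz)
  expect_error(readTrajectory(xyz, grp), "frame 3")
})

test_that("the tube axis is recovered, oriented and equivariant", {
  tj <- simulateTrajectory(nBp = 12, nFrames = 1, seed = 3)
  fr <- frameCoords(tj, 1)
  g <- groupMap(tj)
  sw <- which(g$group == "SWCNT"); an <- which(g$group == "anchor")
  ax <- tubeAxis(fr, sw, an)
  # lattice axis is z; anchors sit at negative z, so the axis points to +z
  expect_lt(max(abs(ax - c(0, 0, 1))), 1e-6)

  R <- randomRotation(4)
  ax2 <- tubeAxis(fr %*% t(R), sw, an)
  expect_lt(max(abs(ax2 - as.vector(R %*% ax))), 1e-6)

  perm <- sample(nrow(fr))
  ax3 <- tubeAxis(fr[perm, ], which(g$group[perm] == "SWCNT"),
                  which(g$group[perm] == "anchor"))
  expect_lt(max(abs(ax3 - ax)), 1e-6)
})

test_that("the duplex axis follows base-pair order and tolerates jitter", {
  bp <- rep(1:12, each = 2)
  rod <- cbind(rep(1:12 * 0.34, each = 2), 0, 0)
  ax <- duplexAxis(rod, seq_len(nrow(rod)), bp)
  expect_lt(max(abs(ax - c(1, 0, 0))), 1e-9)

  # reversing the base-pair ordering flips the axis
  axRev <- duplexAxis(rod, seq_len(nrow(rod)), rev(bp))
  expect_lt(max(abs(axRev + ax)), 1e-9)

  set.seed(5)
  jit <- rod + matrix(rnorm(length(rod), 0, 0.05), ncol = 3)
  axJ <- duplexAxis(jit, seq_len(nrow(jit)), bp)
  expect_lt(tiltAngle(ax, axJ), 2)

  expect_error(duplexAxis(rod, seq_len(nrow(rod)), rep(1, nrow(rod))),
               "base-pair")
})

test_that("tilt angles come from the dot product in degrees", {
  z <- c(0, 0, 1)
  expect_equal(tiltAngle(z, c(1, 0, 0)), 90)
  expect_equal(tiltAngle(z, z), 0)
  u <- c(sin(pi / 3), 0, cos(pi / 3))
  expect_lt(abs(tiltAngle(z, u) - 60), 1e-6)
  expect_equal(tiltAngle(z, -z), 180)
})

test_that("tip-to-surface distances are nearest-atom and isometry-invariant", {
  tj <- simulateTrajectory(nBp = 12, nFrames = 1, tiltMean = 90, seed = 6)
  fr <- frameCoords(tj, 1)
  g <- groupMap(tj)
  sw <- which(g$group == "SWCNT"); tip <- which(g$tip == 1)
  d0 <- tipSurfaceDistance(fr, tip, sw)
  expect_equal(d0, 12 * 0.34, tolerance = 1e-9)

  # coincident tip
  expect_equal(tipSurfaceDistance(fr, sw[1], sw), 0)

  R <- randomRotation(7); shift <- c(3, -2, 5)
  fr2 <- sweep(fr %*% t(R), 2, -shift)
  expect_lt(abs(tipSurfaceDistance(fr2, tip, sw) - d0), 1e-6)
})

test_that("expected duplex lengths use the 0.34 nm/bp rise", {
  expect_identical(expectedDuplexLength(12), 4.08)
  expect_identical(expectedDuplexLength(1), 0.34)
  expect_identical(expectedDuplexLength(24), 8.16)
  expect_equal(expectedDuplexLength(c(12, 15, 18, 20, 24)),
               c(4.08, 5.10, 6.12, 6.80, 8.16))
})

test_that("geometry summaries report order statistics and the tilt correlation", {
  tj <- simulateTrajectory(nBp = 15, nFrames = 200, tiltMean = 90, tiltSd = 15,
                           seed = 8)
  geo <- summarizeGeometry(analyzeTrajectory(tj))
  s <- geo@summary
  expect_true(all(tiltSeries(geo) >= 0 & tiltSeries(geo) <= 180))
  expect_true(all(tipDistanceSeries(geo) > 0))
  # tilting away from perpendicular lowers the tip
  expect_lt(s$tilt_distance_correlation, 0)
  expect_lte(s$angle$p05, s$angle$median)
  expect_lte(s$angle$median, s$angle$p95)

  # constant series: correlation undefined, mean = median = value
  tjc <- simulateTrajectory(nBp = 12, nFrames = 12, tiltMean = 90, tiltSd = 0,
                            seed = 9)
  sc <- summarizeGeometry(analyzeTrajectory(tjc))@summary
  expect_true(is.na(sc$tilt_distance_correlation))
  expect_equal(sc$angle$mean, sc$angle$median)

  # permutation invariance of the summary
  geoP <- geo
  set.seed(10); perm <- sample(length(tiltSeries(geo)))
  geoP@angleDeg <- geo@angleDeg[perm]
  geoP@tipDistanceNm <- geo@tipDistanceNm[perm]
  sp <- summarizeGeometry(geoP)@summary
  expect_equal(sp$angle, s$angle)
  expect_equal(sp$tilt_distance_correlation, s$tilt_distance_correlation)
})

test_that("photon tables and spectra round-trip through their text formats", {
  coh <- simulateCohort(data.frame(mean_tau = 2, sd_tau = 0.1, weight = 1),
                        3, photonParams = cheapPhotonParams(), seed = 11)
  path <- tempfile(fileext = ".csv")
  writePhotonTable(coh$streams, path)
  back <- readPhotonTable(path)
  expect_length(back, sum(vapply(coh$streams, nPhotons, numeric(1)) > 0))
  s1 <- coh$streams[[1]]; b1 <- back[[moleculeId(s1)]]
  expect_equal(macroTime(b1), macroTime(s1), tolerance = 1e-7)
  expect_equal(tcspcWindow(b1), tcspcWindow(s1))

  sp <- makeToySpectra(550, 30, 620, 40)$emission
  spPath <- tempfile(fileext = ".csv")
  writeSpectrum(sp, spPath)
  expect_equal(readSpectrum(spPath)$value, sp$value, tolerance = 1e-10)
})
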