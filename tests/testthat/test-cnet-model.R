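test_that("lifetime-to-efficiency conversion is exact and clips with a flag", {
  expect_equal(efficiencyFromLifetime(3.5, 0, 3.5)$efficiency, 0)
  expect_equal(efficiencyFromLifetime(0, 0, 3.5)$efficiency, 1)
  expect_equal(efficiencyFromLifetime(1.75, 0.1, 3.5)$efficiency, 0.5)
  expect_equal(efficiencyFromLifetime(1.75, 0.14, 3.5)$efficiency_sd, 0.04)

  expect_warning(res <- efficiencyFromLifetime(4.2, 0.05, 3.5), "tau0")
  expect_true(res$clipped)
  expect_equal(res$efficiency, 0)
})

test_that("the distance law is monotone with 50% efficiency at d0", {
  for (n in 1:6) expect_identical(cnetEfficiency(7.4, 7.4, n), 0.5)
  expect_equal(cnetEfficiency(2 * 7.4, 7.4, 5), 1 / 33, tolerance = 1e-15)

  d <- seq(0.5, 40, by = 0.25)
  eta <- cnetEfficiency(d, 7.4, 5)
  expect_true(all(diff(eta) < 0))
  expect_true(all(eta > 0 & eta < 1))
  expect_gt(cnetEfficiency(1e-6, 7.4, 5), 1 - 1e-9)
  expect_lt(cnetEfficiency(1e6, 7.4, 5), 1e-9)
})

test_that("efficiency inversion round-trips to machine precision", {
  expect_equal(invertEfficiency(0.5, 7.4, 5), 7.4, tolerance = 1e-15)
  d <- invertEfficiency(cnetEfficiency(6.9, 7.4, 5), 7.4, 5)
  expect_lt(abs(d - 6.9) / 6.9, 1e-12)
  expect_equal(invertEfficiency(1 / 33, 7.4, 5), 2 * 7.4, tolerance = 1e-12)
  expect_error(invertEfficiency(0, 7.4, 5), "strictly inside")
  expect_error(invertEfficiency(1, 7.4, 5), "strictly inside")
})

test_that("the scaling fit recovers d0 exactly on noiseless points", {
  # distances: trajectory means for the five duplex lengths plus the
  # ~1.1 nm linker-and-dye extension
  d <- c(4.6, 5.0, 5.8, 6.2, 7.7) + 1.1
  pts <- data.frame(d_nm = d, eta = cnetEfficiency(d, 7.4, 5))
  fit <- fitScaling(pts, n = 5)
  expect_lt(abs(characteristicDistance(fit) - 7.4), 1e-6)
  expect_lt(fit@ssr, 1e-12)
  expect_false(fit@nonDiscriminating)

  expect_error(fitScaling(pts[1, ], n = 5), "at least 2")
})

test_that("d0 is recovered within 2% under measurement noise", {
  d <- c(4.6, 5.0, 5.8, 6.2, 7.7) + 1.1
  etaTrue <- cnetEfficiency(d, 7.4, 5)
  set.seed(11)
  d0s <- vapply(1:100, function(i) {
    pts <- data.frame(d_nm = d, eta = etaTrue + rnorm(5, 0, 0.03))
    fitScaling(pts, n = 5)@d0
  }, numeric(1))
  expect_lt(abs(mean(d0s) - 7.4) / 7.4, 0.02)
})

test_that("exponent comparison identifies the generative power law", {
  d <- seq(4, 15, length.out = 12)
  pts4 <- data.frame(d_nm = d, eta = cnetEfficiency(d, 7.4, 4))
  tab <- compareExponents(pts4)
  expect_lt(tab$ssr[tab$exponent == 4], 1e-12)
  expect_lt(tab$ssr[tab$exponent == 5], tab$ssr[tab$exponent == 6])
  expect_lt(tab$ssr[tab$exponent == 5], tab$ssr[tab$exponent == 3])
  expect_identical(tab$rank[tab$exponent == 4], 1L)

  # two points cannot discriminate exponents
  two <- data.frame(d_nm = c(6, 9), eta = cnetEfficiency(c(6, 9), 7.4, 5))
  t2 <- compareExponents(two)
  expect_true(all(t2$non_discriminating))
  expect_lt(t2$ssr[t2$exponent == 5], 1e-12)
})

test_that("the line-acceptor rate integral matches the analytic d^-5 law", {
  d <- c(1, 2, 5, 10, 20, 50)
  num <- lineTransferRate(d, couplingConstant = 2)
  ana <- 2 * (3 * pi / 8) * d^-5
  expect_lt(max(abs(num - ana) / ana), 1e-6)

  r <- lineTransferRate(8) / lineTransferRate(4)
  expect_lt(abs(r - 2^-5) / 2^-5, 1e-6)

  # a wire of fixed length interpolates toward the point-acceptor d^-6 law:
  # the apparent power lies between -5 and -6, and reaches -6 once the wire
  # is much shorter than every probed distance
  dg <- seq(2, 20, length.out = 15)
  slopeAt <- function(L = NULL) {
    k <- suppressWarnings(vapply(dg, function(di)
      lineTransferRate(di, halfLength = L), numeric(1)))
    unname(coef(lm(log(k) ~ log(dg)))[2])
  }
  expect_lt(abs(slopeAt() + 5), 0.01)
  sFinite <- slopeAt(5)
  expect_true(sFinite < -5 && sFinite > -6)
  expect_lt(abs(slopeAt(0.05) + 6), 0.05)
})

test_that("the overlap integral reduces analytically for flat extinction", {
  grid <- seq(420, 740, by = 0.25)
  sp <- makeToySpectra(560, 25, 600, 40, grid = grid)
  flat <- data.frame(wavelength_nm = grid, value = rep(3.7, length(grid)))
  J <- overlapIntegral(sp$emission, flat)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  expectedJ <- 3.7 * trapz(grid, sp$emission$value * grid^4)
  expect_equal(J, expectedJ, tolerance = 1e-9)

  zero <- data.frame(wavelength_nm = grid, value = rep(0, length(grid)))
  expect_equal(overlapIntegral(sp$emission, zero), 0)

  # emission amplitude cancels through normalization
  em2 <- sp$emission; em2$value <- 2 * em2$value
  expect_equal(overlapIntegral(em2, sp$absorption),
               overlapIntegral(sp$emission, sp$absorption), tolerance = 1e-12)

  far <- data.frame(wavelength_nm = seq(900, 1000, 1), value = rep(1, 101))
  expect_warning(jd <- overlapIntegral(sp$emission, far), "overlap")
  expect_identical(jd, 0)
})

test_that("Forster-radius ratios are reciprocal and scale as the sixth root", {
  expect_equal(forsterRatio(2, 0.5, 1, 1), 1)
  expect_equal(forsterRatio(64, 1, 1, 1), 2)
  set.seed(12)
  for (i in 1:1000) {
    v <- exp(rnorm(4))
    expect_lt(abs(forsterRatio(v[1], v[2], v[3], v[4]) *
                    forsterRatio(v[3], v[4], v[1], v[2]) - 1), 1e-12)
  }
  expect_error(forsterRatio(-1, 1, 1, 1), "positive")
})
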