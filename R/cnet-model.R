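#' Quenching efficiency from a fluorescence lifetime
#'
#' `eta = 1 - tau/tau0`, with `sigma_eta = sigma_tau / tau0` (the unquenched
#' lifetime is treated as exact). Values outside `[0, 1]` are clipped and
#' flagged rather than rejected; a lifetime exceeding `tau0` by more than
#' three standard errors triggers a warning, since apparent super-radiance is
#' physically suspect.
#'
#' @param tau fitted lifetime(s), ns.
#' @param tauSd lifetime standard error(s), ns.
#' @param tau0 unquenched lifetime, ns, > 0.
#' @return data.frame with columns `efficiency`, `efficiency_sd`, `clipped`.
#' @examples
#' efficiencyFromLifetime(1.75, 0.05, 3.5)   # eta = 0.5
#' @export
efficiencyFromLifetime <- function(tau, tauSd = 0, tau0) {
  .stopIfNot(tau0 > 0, "tau0 must be positive (got %g)", tau0)
  .stopIfNot(all(tau >= 0), "tau must be non-negative")
  tauSd <- rep_len(tauSd, length(tau))
  if (any(tau > tau0 + 3 * tauSd))
    warning("lifetime exceeds tau0 by more than 3 sigma; check tau0 reference")
  eta <- 1 - tau / tau0
  clipped <- eta < 0 | eta > 1
  data.frame(efficiency = pmin(pmax(eta, 0), 1),
             efficiency_sd = tauSd / tau0, clipped = clipped)
}

#' CNET distance law
#'
#' Quenching efficiency of a point-like donor near a 1D acceptor at distance
#' `d`: `eta = 1 / (1 + (d/d0)^n)`. At `d = d0` the efficiency is exactly
#' 50%; for SWCNT acceptors `n = 5`.
#'
#' @param d distance(s), nm, > 0.
#' @param d0 characteristic distance, nm, > 0.
#' @param n exponent, >= 1.
#' @return efficiency in (0, 1).
#' @export
cnetEfficiency <- function(d, d0, n = 5) {
  .stopIfNot(all(d > 0), "d must be positive")
  .stopIfNot(d0 > 0, "d0 must be positive (got %g)", d0)
  .stopIfNot(n >= 1, "n must be >= 1 (got %g)", n)
  1 / (1 + (d / d0)^n)
}

#' Invert the CNET distance law
#'
#' @param eta efficiency, strictly inside (0, 1).
#' @param d0 characteristic distance (nm).
#' @param n exponent.
#' @return distance `d = d0 * (1/eta - 1)^(1/n)` (nm).
#' @export
invertEfficiency <- function(eta, d0, n = 5) {
  .stopIfNot(all(eta > 0 & eta < 1),
             "eta must lie strictly inside (0, 1): the distance is unbounded or zero at the limits")
  .stopIfNot(d0 > 0, "d0 must be positive (got %g)", d0)
  d0 * (1 / eta - 1)^(1 / n)
}

# Sum of squared (optionally weighted) residuals of the law at fixed n.
.scalingSsr <- function(d0, d, eta, n, w) sum(w * (eta - cnetEfficiency(d, d0, n))^2)

#' Fit the distance law to quenching points
#'
#' One-parameter least squares of `eta = 1/(1 + (d/d0)^n)` over `d0` with
#' the exponent held fixed: a coarse logarithmic grid over
#' `d0 in [0.5, 50] nm` followed by golden-section refinement
#' ([stats::optimize()]), so the fit is deterministic given its inputs.
#' The standard error of `d0` comes from the Jacobian at the optimum.
#'
#' @param points data.frame of quenching points with columns `d_nm`, `eta`
#'   and (for weighted fits) `eta_sd`.
#' @param n fixed exponent.
#' @param weighted inverse-variance weighting by `eta_sd^2` (default
#'   unweighted).
#' @param d0Bounds search interval for d0 (nm).
#' @return a [ScalingFit-class]. With only two points the fit is flagged
#'   non-discriminating (a one-parameter law through two points cannot rank
#'   exponents).
#' @export
fitScaling <- function(points, n = 5, weighted = FALSE,
                       d0Bounds = c(0.5, 50)) {
  .stopIfNot(is.data.frame(points) && all(c("d_nm", "eta") %in% names(points)),
             "points must be a data.frame with columns d_nm and eta")
  npt <- nrow(points)
  .stopIfNot(npt >= 2, "at least 2 quenching points are required (got %d)", npt)
  d <- points$d_nm; eta <- points$eta
  .stopIfNot(all(d > 0), "distances must be positive")
  w <- if (weighted) {
    .stopIfNot("eta_sd" %in% names(points) && all(points$eta_sd > 0),
               "weighted fit needs positive eta_sd")
    1 / points$eta_sd^2
  } else rep(1, npt)

  grid <- exp(seq(log(d0Bounds[1]), log(d0Bounds[2]), length.out = 200))
  ssrGrid <- vapply(grid, .scalingSsr, numeric(1), d = d, eta = eta, n = n, w = w)
  k <- which.min(ssrGrid)
  lo <- grid[max(k - 1L, 1L)]; hi <- grid[min(k + 1L, length(grid))]
  opt <- stats::optimize(.scalingSsr, c(lo, hi), d = d, eta = eta, n = n, w = w,
                         tol = 1e-10)
  d0 <- opt$minimum
  ssr <- .scalingSsr(d0, d, eta, n, w)

  # d eta / d d0 at the optimum
  r <- (d / d0)^n
  J <- n * r / (d0 * (1 + r)^2)
  dof <- max(npt - 1L, 1L)
  s2 <- ssr / dof
  d0Se <- if (sum(w * J^2) > 0) sqrt(s2 / sum(w * J^2)) else Inf

  atBound <- d0 <= d0Bounds[1] * 1.001 || d0 >= d0Bounds[2] * 0.999
  new("ScalingFit", exponent = n, d0 = d0, d0Se = d0Se, ssr = ssr,
      nPoints = npt, weighted = weighted, atBound = atBound,
      nonDiscriminating = npt < 3)
}

#' Compare distance-law exponents
#'
#' Fits the law once per candidate exponent (each with its own optimal d0)
#' and ranks the exponents by residual sum of squares.
#'
#' @param points quenching points as in [fitScaling()].
#' @param exponents candidate exponents, subset of 3:6.
#' @param weighted passed to [fitScaling()].
#' @return data.frame with columns `exponent`, `d0_nm`, `d0_se_nm`, `ssr`,
#'   `rank`, `non_discriminating`; fits attached as attribute `"fits"`.
#' @export
compareExponents <- function(points, exponents = c(3, 4, 5, 6),
                             weighted = FALSE) {
  .stopIfNot(all(exponents %in% 3:6), "exponents must be a subset of 3:6")
  fits <- lapply(exponents, function(n) fitScaling(points, n, weighted))
  tab <- data.frame(
    exponent = exponents,
    d0_nm = vapply(fits, function(f) f@d0, numeric(1)),
    d0_se_nm = vapply(fits, function(f) f@d0Se, numeric(1)),
    ssr = vapply(fits, function(f) f@ssr, numeric(1))
  )
  tab$rank <- rank(tab$ssr, ties.method = "first")
  tab$non_discriminating <- vapply(fits, function(f) f@nonDiscriminating, logical(1))
  attr(tab, "fits") <- fits
  tab
}

#' Energy-transfer rate from a point donor to a line acceptor
#'
#' Integrates the near-field transfer rate of a point-like donor at height
#' `d` above a line of acceptors, `k(d) = C * Int (d^2 + x^2)^-3 dx`, by
#' composite Simpson quadrature over `[-halfLength, halfLength]`. For an
#' effectively infinite wire the integral is `C * (3*pi/8) * d^-5`, which is
#' the origin of the d^-5 distance law for SWCNT acceptors; truncating the
#' wire pushes the apparent power toward the point-acceptor d^-6 limit.
#'
#' @param d donor--line distance(s), nm, > 0.
#' @param couplingConstant prefactor C (arbitrary rate units).
#' @param halfLength half-length of the wire (nm); default `200 * d`
#'   (effectively infinite). Below `10 * d` a truncation warning is issued.
#' @param quadratureStep Simpson step (nm); default `d / 100`.
#' @return transfer rate(s), same length as `d`.
#' @export
lineTransferRate <- function(d, couplingConstant = 1, halfLength = NULL,
                             quadratureStep = NULL) {
  .stopIfNot(all(d > 0), "d must be positive")
  one <- function(di) {
    L <- if (is.null(halfLength)) 200 * di else halfLength
    h <- if (is.null(quadratureStep)) di / 100 else quadratureStep
    if (L < 10 * di)
      warning("halfLength < 10*d: finite-wire truncation is significant")
    nInt <- max(2L, 2L * ceiling(L / h))      # even number of intervals
    x <- seq(-L, L, length.out = nInt + 1L)
    f <- (di^2 + x^2)^(-3)
    wts <- c(1, rep(c(4, 2), length.out = nInt - 1L), 1)
    couplingConstant * sum(wts * f) * (x[2] - x[1]) / 3
  }
  vapply(d, one, numeric(1))
}

#' Spectral overlap integral
#'
#' `J = Int Fbar_D(lambda) * eps_A(lambda) * lambda^4 dlambda`, with the
#' donor emission `Fbar_D` area-normalized. Both spectra are linearly
#' interpolated onto the union of their grids restricted to the overlapping
#' wavelength range; quadrature is trapezoidal.
#'
#' @param emission data.frame `wavelength_nm`, `value` (donor emission,
#'   arbitrary units).
#' @param extinction data.frame `wavelength_nm`, `value` (acceptor molar
#'   extinction, M^-1 cm^-1).
#' @return `J` in M^-1 cm^-1 nm^4 (0 with a warning for disjoint grids).
#' @export
overlapIntegral <- function(emission, extinction) {
  for (s in list(emission, extinction))
    .stopIfNot(is.data.frame(s) && all(c("wavelength_nm", "value") %in% names(s)) &&
               nrow(s) >= 2 && all(diff(s$wavelength_nm) > 0) && all(s$value >= 0),
               "spectra must be data.frames with increasing wavelength_nm and values >= 0")
  lo <- max(min(emission$wavelength_nm), min(extinction$wavelength_nm))
  hi <- min(max(emission$wavelength_nm), max(extinction$wavelength_nm))
  if (lo >= hi) {
    warning("spectra grids do not overlap; J = 0")
    return(0)
  }
  lam <- sort(unique(c(
    emission$wavelength_nm[emission$wavelength_nm >= lo & emission$wavelength_nm <= hi],
    extinction$wavelength_nm[extinction$wavelength_nm >= lo & extinction$wavelength_nm <= hi],
    lo, hi)))
  Fd <- stats::approx(emission$wavelength_nm, emission$value, lam)$y
  # normalize over the donor's own full grid, not just the overlap window
  Fnorm <- .trapz(emission$wavelength_nm, emission$value)
  .stopIfNot(Fnorm > 0, "emission spectrum has zero area")
  epsA <- stats::approx(extinction$wavelength_nm, extinction$value, lam)$y
  .trapz(lam, (Fd / Fnorm) * epsA * lam^4)
}

#' Ratio of Forster radii of two donors sharing one acceptor
#'
#' `R0(1)/R0(2) = ((J1*QY1) / (J2*QY2))^(1/6)`, assuming equal refractive
#' index and freely rotating dyes (orientation factors cancel).
#'
#' @param J1,QY1 overlap integral and quantum yield of donor 1.
#' @param J2,QY2 overlap integral and quantum yield of donor 2.
#' @return the dimensionless Forster-radius ratio.
#' @export
forsterRatio <- function(J1, QY1, J2, QY2) {
  .stopIfNot(all(c(J1, QY1, J2, QY2) > 0), "all inputs must be positive")
  ((J1 * QY1) / (J2 * QY2))^(1 / 6)
}
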