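#' Simulate a single-molecule photon stream
#'
#' Generates the TCSPC photon record of one surface-immobilized dye under
#' pulsed excitation. Signal photons arrive as a Poisson process at
#' `brightness` counts/s until a single photobleaching event (exponentially
#' distributed with rate `bleachRate`); each signal micro-time is an IRF draw
#' (Gaussian, width `irfSigma`, centred at `irfOffset`) plus an exponential
#' decay draw with mean `trueTau`, wrapped modulo the excitation period.
#' Background photons arrive uniformly over the whole acquisition with
#' uniform micro-times. Photons whose wrapped micro-time falls outside the
#' TCSPC window are discarded (undetected).
#'
#' @param trueTau ground-truth fluorescence lifetime (ns), > 0.
#' @param irfSigma Gaussian IRF width (ns), >= 0.
#' @param brightness signal count rate before bleaching (counts/s).
#' @param backgroundRate background count rate (counts/s).
#' @param bleachRate photobleaching rate (1/s); 0 means no bleaching.
#' @param duration acquisition time (s), > 0.
#' @param excitationPeriod laser repetition period (ns).
#' @param tcspcWindow TCSPC detection window (ns), <= `excitationPeriod`.
#' @param irfOffset IRF arrival offset within the window (ns).
#' @param moleculeId identifier for the stream.
#' @param populationLabel label copied into the ground truth.
#' @param trueDistance optional ground-truth dye--SWCNT distance (nm).
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so cohort generators control reproducibility globally).
#' @return list with elements `stream` ([PhotonStream-class]) and `truth`
#'   (one-row data.frame: `molecule_id`, `true_tau_ns`,
#'   `true_background_fraction`, `bleach_time_s`, `population`,
#'   `true_distance_nm`).
#' @examples
#' sim <- simulatePhotonStream(trueTau = 3.5, brightness = 5e3,
#'                             backgroundRate = 100, bleachRate = 0.5,
#'                             duration = 5, seed = 1)
#' sim$stream
#' @export
simulatePhotonStream <- function(trueTau, irfSigma = 0.1, brightness,
                                 backgroundRate = 0, bleachRate = 0,
                                 duration, excitationPeriod = 25,
                                 tcspcWindow = excitationPeriod,
                                 irfOffset = 2, moleculeId = "mol_1",
                                 populationLabel = NA_character_,
                                 trueDistance = NA_real_, seed = NULL) {
  .stopIfNot(trueTau > 0, "trueTau must be positive (got %g)", trueTau)
  .stopIfNot(duration > 0, "duration must be positive (got %g)", duration)
  .stopIfNot(irfSigma >= 0, "irfSigma must be non-negative (got %g)", irfSigma)
  .stopIfNot(brightness >= 0, "brightness must be non-negative (got %g)", brightness)
  .stopIfNot(backgroundRate >= 0, "backgroundRate must be non-negative (got %g)", backgroundRate)
  .stopIfNot(bleachRate >= 0, "bleachRate must be non-negative (got %g)", bleachRate)
  if (!is.null(seed)) set.seed(seed)

  bleachTime <- if (bleachRate > 0) stats::rexp(1, bleachRate) else Inf
  tSignal <- min(bleachTime, duration)

  nSig <- stats::rpois(1, brightness * tSignal)
  sigMacro <- sort(stats::runif(nSig, 0, tSignal))
  sigMicro <- (irfOffset +
                 stats::rnorm(nSig, 0, irfSigma) +
                 stats::rexp(nSig, 1 / trueTau)) %% excitationPeriod

  nBg <- stats::rpois(1, backgroundRate * duration)
  bgMacro <- stats::runif(nBg, 0, duration)
  bgMicro <- stats::runif(nBg, 0, excitationPeriod)

  macro <- c(sigMacro, bgMacro)
  micro <- c(sigMicro, bgMicro)
  keep <- micro < tcspcWindow
  macro <- macro[keep]; micro <- micro[keep]
  ord <- order(macro)

  stream <- PhotonStream(moleculeId, macro[ord], micro[ord],
                         tcspcWindow, excitationPeriod)
  nTot <- length(macro)
  truth <- data.frame(
    molecule_id = moleculeId,
    true_tau_ns = trueTau,
    true_background_fraction = if (nTot) sum(keep[-seq_len(nSig)]) / nTot else 0,
    bleach_time_s = min(bleachTime, duration),
    population = populationLabel,
    true_distance_nm = trueDistance,
    stringsAsFactors = FALSE
  )
  list(stream = stream, truth = truth)
}

#' Simulate a cohort of molecules from Gaussian lifetime subpopulations
#'
#' Draws each molecule's ground-truth lifetime from a mixture of Gaussian
#' components (truncated at 0.05 ns, the shortest lifetime the instrument
#' model resolves) and simulates its photon stream. This emulates a
#' per-duplex-length dataset in which heterogeneous duplex conformations
#' produce distinct lifetime subpopulations.
#'
#' @param populations data.frame with columns `mean_tau`, `sd_tau`, `weight`
#'   (weights normalized internally) and optionally `label`.
#' @param nMolecules number of molecules.
#' @param photonParams named list of arguments passed to
#'   [simulatePhotonStream()] (e.g. `brightness`, `duration`, `bleachRate`,
#'   `backgroundRate`, `irfSigma`).
#' @param seed integer seed.
#' @param tauFloor truncation floor for lifetime draws (ns).
#' @return list with `streams` (list of [PhotonStream-class]) and `truth`
#'   (data.frame, one row per molecule).
#' @export
simulateCohort <- function(populations, nMolecules, photonParams = list(),
                           seed = 1, tauFloor = 0.05) {
  .stopIfNot(is.data.frame(populations) && nrow(populations) > 0,
             "populations must be a non-empty data.frame")
  .stopIfNot(all(c("mean_tau", "sd_tau", "weight") %in% names(populations)),
             "populations needs columns mean_tau, sd_tau, weight")
  .stopIfNot(all(populations$weight > 0), "weights must be positive")
  .stopIfNot(all(populations$mean_tau - 3 * populations$sd_tau > 0),
             "each component needs mean_tau - 3*sd_tau > 0")
  set.seed(seed)

  w <- populations$weight / sum(populations$weight)
  labs <- if ("label" %in% names(populations)) as.character(populations$label)
          else sprintf("pop%d", seq_len(nrow(populations)))
  comp <- sample.int(nrow(populations), nMolecules, replace = TRUE, prob = w)

  streams <- vector("list", nMolecules)
  truth <- vector("list", nMolecules)
  for (i in seq_len(nMolecules)) {
    tau <- .rtruncnorm(1, populations$mean_tau[comp[i]],
                       populations$sd_tau[comp[i]], lower = tauFloor)
    args <- c(list(trueTau = tau, moleculeId = sprintf("mol_%04d", i),
                   populationLabel = labs[comp[i]]), photonParams)
    sim <- do.call(simulatePhotonStream, args)
    streams[[i]] <- sim$stream
    truth[[i]] <- sim$truth
  }
  list(streams = streams, truth = do.call(rbind, truth))
}

#' Geometric forward model: tilt angle to distance to lifetime
#'
#' Maps duplex geometry to ground-truth lifetimes through the CNET distance
#' law. Per molecule a tilt angle theta (to the tube axis, degrees) is drawn
#' from a truncated Gaussian on (0, 180); the dye height is
#' `d = n_bp * rise * sin(theta) + linkerOffset` (theta = 90 maximizes the
#' height), the quenching efficiency is `eta = 1/(1 + (d/d0)^exponent)` and
#' the lifetime is `tau0 * (1 - eta)`.
#'
#' @param nBp duplex length in base pairs.
#' @param rise helical rise per base pair (nm/bp), default 0.34 (B-DNA).
#' @param linkerOffset added linker + dye extension (nm), default 1.1.
#' @param tiltMean,tiltSd tilt-angle distribution (degrees).
#' @param d0 characteristic 50%-efficiency distance (nm), > 0.
#' @param exponent distance-law exponent, one of 3, 4, 5, 6.
#' @param tau0 unquenched lifetime (ns).
#' @param nMolecules number of molecules.
#' @param seed integer seed.
#' @param populationLabel label stored with each molecule.
#' @return data.frame with per-molecule `tilt_deg`, `true_distance_nm`,
#'   `true_eta`, `true_tau_ns`, `population`.
#' @export
geometryForwardModel <- function(nBp, rise = 0.34, linkerOffset = 1.1,
                                 tiltMean = 90, tiltSd = 0, d0 = 7.4,
                                 exponent = 5, tau0 = 3.5, nMolecules = 1,
                                 seed = 1,
                                 populationLabel = sprintf("%dbp", nBp)) {
  .stopIfNot(d0 > 0, "d0 must be positive (got %g)", d0)
  .stopIfNot(exponent %in% c(3, 4, 5, 6), "exponent must be one of 3,4,5,6")
  set.seed(seed)
  theta <- .rtruncnorm(nMolecules, tiltMean, tiltSd,
                       lower = .Machine$double.eps, upper = 180 - .Machine$double.eps)
  d <- nBp * rise * sin(theta * pi / 180) + linkerOffset
  eta <- cnetEfficiency(d, d0, exponent)
  data.frame(
    molecule_id = sprintf("mol_%04d", seq_len(nMolecules)),
    tilt_deg = theta,
    true_distance_nm = d,
    true_eta = eta,
    true_tau_ns = tau0 * (1 - eta),
    population = populationLabel,
    stringsAsFactors = FALSE
  )
}

#' Simulate a rigid duplex-on-cylinder trajectory
#'
#' Builds a coarse-grained stand-in for an MD trajectory of a DNA duplex
#' anchored on an SWCNT: the tube is a fixed helical-ring lattice of
#' pseudo-atoms on a cylinder (axis = z), a short anchor strand lies on the
#' surface on the negative-z side, and each frame places a rigid duplex rod
#' at the surface attachment point with a per-frame tilt angle to the tube
#' axis drawn from a truncated Gaussian and an azimuth rotating the tilt
#' direction about the surface normal. Capture and complementary strand
#' pseudo-atoms sit on the rod axis; the final complementary atom (at
#' `nBp * rise` from the surface) is the flagged 5'-tip.
#'
#' @param nBp duplex length (bp).
#' @param nFrames number of frames, >= 1.
#' @param tiltMean,tiltSd tilt distribution (degrees, truncated to (0, 180)).
#' @param azimuthMean,azimuthSd azimuth distribution (degrees).
#' @param cylinderRadius tube radius (nm), default 0.38 (a (6,5) tube).
#' @param rise rise per base pair (nm/bp).
#' @param seed integer seed.
#' @param latticeStep approximate SWCNT lattice spacing (nm).
#' @return a [TrajectoryFrameSet-class].
#' @export
simulateTrajectory <- function(nBp, nFrames = 100, tiltMean = 90, tiltSd = 0,
                               azimuthMean = 0, azimuthSd = 0,
                               cylinderRadius = 0.38, rise = 0.34, seed = 1,
                               latticeStep = 0.15) {
  .stopIfNot(nFrames >= 1, "nFrames must be >= 1")
  .stopIfNot(cylinderRadius > 0, "cylinderRadius must be positive (got %g)",
             cylinderRadius)
  .stopIfNot(nBp >= 1, "nBp must be >= 1")
  set.seed(seed)

  r <- cylinderRadius
  rodLen <- nBp * rise
  # symmetric ring grid including z = 0, so the lattice covariance is exactly
  # axial and a lattice atom sits at the duplex attachment point
  half <- ceiling((rodLen + 1) / latticeStep)
  zRing <- (-half:half) * latticeStep
  nPhi <- max(8L, ceiling(2 * pi * r / latticeStep))
  phi <- seq(0, 2 * pi, length.out = nPhi + 1L)[-(nPhi + 1L)]
  lattice <- cbind(
    x = rep(r * cos(phi), times = length(zRing)),
    y = rep(r * sin(phi), times = length(zRing)),
    z = rep(zRing, each = nPhi)
  )
  # guarantee a lattice atom exactly at the duplex attachment point (r, 0, 0)
  if (!any(abs(lattice[, 1] - r) < 1e-12 & abs(lattice[, 2]) < 1e-12 &
           abs(lattice[, 3]) < 1e-12))
    lattice <- rbind(lattice, c(r, 0, 0))
  nSw <- nrow(lattice)

  # anchor pseudo-atoms on the surface, negative-z side of the attachment
  zAnchor <- seq(-1.6, -0.4, by = 0.3)
  anchor <- cbind(x = rep(r, length(zAnchor)), y = rep(0, length(zAnchor)),
                  z = zAnchor)
  nAn <- nrow(anchor)

  nDup <- 2L * nBp                     # capture + complement, one atom per bp
  groups <- data.frame(
    atom_index = seq_len(nSw + nAn + nDup) - 1L,
    group = c(rep("SWCNT", nSw), rep("anchor", nAn),
              rep(c("capture", "complement"), each = nBp)),
    bp_index = c(rep(-1L, nSw + nAn), seq_len(nBp), seq_len(nBp)),
    tip = 0L,
    stringsAsFactors = FALSE
  )
  groups$tip[nSw + nAn + nDup] <- 1L   # 5'-terminal complement atom

  theta <- .rtruncnorm(nFrames, tiltMean, tiltSd,
                       lower = 1e-9, upper = 180 - 1e-9) * pi / 180
  azim <- stats::rnorm(nFrames, azimuthMean, azimuthSd) * pi / 180
  base <- c(r, 0, 0)
  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    # rod direction: angle theta to the tube axis (z); azimuth rotates the
    # perpendicular component from the outward normal (x) toward y
    u <- c(sin(theta[f]) * cos(azim[f]), sin(theta[f]) * sin(azim[f]),
           cos(theta[f]))
    kCap <- (seq_len(nBp) - 0.25) * rise
    kCom <- seq_len(nBp) * rise
    rod <- rbind(t(base + outer(u, kCap)), t(base + outer(u, kCom)))
    fr <- rbind(lattice, anchor, rod)
    dimnames(fr) <- list(NULL, c("x", "y", "z"))
    frames[[f]] <- fr
  }
  new("TrajectoryFrameSet", frames = frames, groups = groups,
      cylinderRadius = r, nBp = nBp)
}

#' Build toy emission and absorption spectra
#'
#' Gaussian band shapes on a shared wavelength grid; the emission band is
#' area-normalized (trapezoid rule) for use in the overlap integral.
#'
#' @param emissionPeak,emissionFwhm donor emission band centre and FWHM (nm).
#' @param absorptionPeak,absorptionFwhm acceptor absorption band centre and
#'   FWHM (nm).
#' @param grid strictly increasing wavelength grid (nm), >= 10 points.
#' @param absorptionMax peak molar extinction (M^-1 cm^-1).
#' @return list with data.frames `emission` and `absorption`, each with
#'   columns `wavelength_nm`, `value`.
#' @export
makeToySpectra <- function(emissionPeak, emissionFwhm,
                           absorptionPeak, absorptionFwhm,
                           grid = seq(400, 1200, by = 1),
                           absorptionMax = 1e5) {
  .stopIfNot(emissionPeak > 0 && emissionFwhm > 0 &&
             absorptionPeak > 0 && absorptionFwhm > 0,
             "peaks and widths must be positive")
  .stopIfNot(length(grid) >= 10 && all(diff(grid) > 0),
             "grid must be strictly increasing with at least 10 points")
  covers <- function(peak, fwhm)
    min(grid) <= peak - 3 * fwhm && max(grid) >= peak + 3 * fwhm
  if (!covers(emissionPeak, emissionFwhm) || !covers(absorptionPeak, absorptionFwhm))
    warning("grid does not cover +/- 3 FWHM of both bands; truncated spectra")

  gband <- function(peak, fwhm) exp(-((grid - peak)^2) / (2 * (fwhm / 2.3548200450309493)^2))
  em <- gband(emissionPeak, emissionFwhm)
  area <- .trapz(grid, em)
  .stopIfNot(area > 0, "emission band has zero area on the grid")
  list(
    emission = data.frame(wavelength_nm = grid, value = em / area),
    absorption = data.frame(wavelength_nm = grid,
                            value = absorptionMax * gband(absorptionPeak, absorptionFwhm))
  )
}
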