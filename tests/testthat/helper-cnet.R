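# Shared fixtures for the test suite. Everything is generated in code.

# photon parameters of a bright, bleaching molecule: ~2e4 signal photons,
# ~2% background, as in the single-molecule acquisitions the pipeline targets
brightPhotonParams <- function() {
  list(brightness = 2e4, duration = 5, bleachRate = 1,
       backgroundRate = 200, irfSigma = 0.1)
}

# cheap photon parameters for tests that only need plumbing, not precision
cheapPhotonParams <- function() {
  list(brightness = 2e3, duration = 1, bleachRate = 2,
       backgroundRate = 50, irfSigma = 0.1)
}

# a decay curve simulated without bleaching, with expected nPhotons photons
simulateDecay <- function(tau, nPhotons = 2e4, bgFraction = 0.02,
                          irfSigma = 0.1, seed = 1, period = 25,
                          window = period, irfOffset = 2) {
  bgRate <- bgFraction / (1 - bgFraction) * nPhotons
  sim <- simulatePhotonStream(trueTau = tau, irfSigma = irfSigma,
                              brightness = nPhotons, backgroundRate = bgRate,
                              bleachRate = 0, duration = 1,
                              excitationPeriod = period, tcspcWindow = window,
                              irfOffset = irfOffset, seed = seed)
  buildDecay(sim$stream, postBleachExclusion = FALSE)
}

# Poisson intensity trace with piecewise-constant rates (counts per bin)
pieceTrace <- function(levels, lengths, binWidth = 0.01) {
  counts <- stats::rpois(sum(lengths), rep(levels, lengths))
  new("IntensityTrace",
      binEdges = seq(0, sum(lengths) * binWidth, by = binWidth),
      counts = as.numeric(counts))
}

# rigid-body transform of every frame in a trajectory
transformTrajectory <- function(traj, R, shift) {
  traj@frames <- lapply(traj@frames, function(f)
    sweep(f %*% t(R), 2, -shift))
  traj
}

# random rotation matrix from a seed
randomRotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}
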