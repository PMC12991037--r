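#' @import methods
NULL

# ---- PhotonStream -----------------------------------------------------------

#' Single-molecule photon stream
#'
#' Container for the detection events of one molecule in a pulsed-excitation
#' (TCSPC) experiment. Each event carries a macro time (wall-clock arrival, in
#' seconds) and a micro time (delay after the excitation pulse, in
#' nanoseconds). The micro-time axis is periodic with the excitation period;
#' detection is restricted to a TCSPC window no longer than that period.
#'
#' @slot moleculeId single identifier string.
#' @slot macroTime numeric vector of arrival times in seconds, non-decreasing.
#' @slot microTime numeric vector of TCSPC delays in nanoseconds, in
#'   `[0, tcspcWindow)`.
#' @slot tcspcWindow TCSPC detection window in nanoseconds.
#' @slot excitationPeriod laser repetition period in nanoseconds;
#'   `tcspcWindow <= excitationPeriod`.
#' @exportClass PhotonStream
setClass("PhotonStream",
  slots = c(
    moleculeId       = "character",
    macroTime        = "numeric",
    microTime        = "numeric",
    tcspcWindow      = "numeric",
    excitationPeriod = "numeric"
  )
)

setValidity("PhotonStream", function(object) {
  msg <- character()
  if (length(object@moleculeId) != 1L) msg <- c(msg, "moleculeId must be a single string")
  if (length(object@macroTime) != length(object@microTime))
    msg <- c(msg, "macroTime and microTime must have equal length")
  if (length(object@macroTime) > 1L && any(diff(object@macroTime) < 0))
    msg <- c(msg, "macroTime must be non-decreasing")
  if (length(object@microTime) &&
      (any(object@microTime < 0) || any(object@microTime >= object@tcspcWindow)))
    msg <- c(msg, "microTime must lie in [0, tcspcWindow)")
  if (object@tcspcWindow > object@excitationPeriod + 1e-12)
    msg <- c(msg, "tcspcWindow must not exceed excitationPeriod")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotonStream
#'
#' @param moleculeId identifier string.
#' @param macroTime arrival times (s).
#' @param microTime TCSPC delays (ns).
#' @param tcspcWindow TCSPC window (ns).
#' @param excitationPeriod excitation period (ns), default equal to the window.
#' @return a [PhotonStream-class] object.
#' @export
PhotonStream <- function(moleculeId, macroTime, microTime,
                         tcspcWindow, excitationPeriod = tcspcWindow) {
  new("PhotonStream",
      moleculeId = as.character(moleculeId),
      macroTime = as.numeric(macroTime), microTime = as.numeric(microTime),
      tcspcWindow = as.numeric(tcspcWindow),
      excitationPeriod = as.numeric(excitationPeriod))
}

#' @describeIn PhotonStream number of detected photons.
#' @param object,x a `PhotonStream`.
#' @export
nPhotons <- function(x) {
  if (is(x, "PhotonStream")) length(x@macroTime)
  else if (is(x, "DecayCurve")) sum(x@counts)
  else stop("nPhotons() not defined for this class")
}

#' @export
moleculeId <- function(x) x@moleculeId

#' @export
macroTime <- function(x) x@macroTime

#' @export
microTime <- function(x) x@microTime

#' @export
tcspcWindow <- function(x) x@tcspcWindow

setMethod("show", "PhotonStream", function(object) {
  cat("PhotonStream '", object@moleculeId, "': ",
      length(object@macroTime), " photons over ",
      if (length(object@macroTime)) sprintf("%.3g s", max(object@macroTime)) else "0 s",
      "; TCSPC window ", object@tcspcWindow, " ns\n", sep = "")
})

# ---- IntensityTrace / DecayCurve -------------------------------------------

#' Binned intensity time trace
#'
#' @slot binEdges bin edges in seconds (length = length(counts) + 1).
#' @slot counts photon counts per bin.
#' @exportClass IntensityTrace
setClass("IntensityTrace", slots = c(binEdges = "numeric", counts = "numeric"))

setValidity("IntensityTrace", function(object) {
  if (length(object@binEdges) != length(object@counts) + 1L)
    return("length(binEdges) must be length(counts) + 1")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' @export
binEdges <- function(x) x@binEdges

#' @export
binCounts <- function(x) x@counts

setMethod("show", "IntensityTrace", function(object) {
  cat("IntensityTrace: ", length(object@counts), " bins, ",
      sum(object@counts), " photons\n", sep = "")
})

#' TCSPC decay histogram
#'
#' Histogram of photon micro-times over the TCSPC window, with uniform bins.
#'
#' @slot binEdges uniform bin edges in ns over `[0, tcspcWindow]`.
#' @slot counts photon counts per bin.
#' @slot tcspcWindow window length (ns).
#' @slot excitationPeriod excitation period (ns).
#' @exportClass DecayCurve
setClass("DecayCurve",
  slots = c(binEdges = "numeric", counts = "numeric",
            tcspcWindow = "numeric", excitationPeriod = "numeric"))

setValidity("DecayCurve", function(object) {
  w <- diff(object@binEdges)
  if (length(object@binEdges) != length(object@counts) + 1L)
    return("length(binEdges) must be length(counts) + 1")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(w) && diff(range(w)) > 1e-9 * mean(w)) return("bins must be uniform")
  TRUE
})

setMethod("show", "DecayCurve", function(object) {
  cat("DecayCurve: ", length(object@counts), " bins over [0, ",
      object@tcspcWindow, ") ns, ", sum(object@counts), " photons\n", sep = "")
})

# ---- LifetimeFit ------------------------------------------------------------

#' Monoexponential lifetime fit result
#'
#' @slot tau fitted lifetime (ns).
#' @slot tauSe standard error of tau from the observed information (ns).
#' @slot backgroundFraction fitted flat-background fraction in `[0,1]`.
#' @slot irfSigma IRF width used (ns).
#' @slot t0 fitted IRF arrival offset (ns).
#' @slot logLik maximized (multinomial) log-likelihood.
#' @slot nPhotons photons in the fitted decay.
#' @slot converged optimizer convergence flag.
#' @slot pinned TRUE when tau finished at a box bound.
#' @slot fitMode "mle" or "lsq".
#' @exportClass LifetimeFit
setClass("LifetimeFit",
  slots = c(tau = "numeric", tauSe = "numeric", backgroundFraction = "numeric",
            irfSigma = "numeric", t0 = "numeric", logLik = "numeric",
            nPhotons = "numeric", converged = "logical", pinned = "logical",
            fitMode = "character"))

#' @export
lifetime <- function(x) x@tau

#' @export
lifetimeSe <- function(x) x@tauSe

#' @export
isConverged <- function(x) isTRUE(x@converged)

setMethod("show", "LifetimeFit", function(object) {
  cat(sprintf("LifetimeFit (%s): tau = %.4g +/- %.2g ns, b = %.3g, n = %d, %s\n",
              object@fitMode, object@tau, object@tauSe,
              object@backgroundFraction, as.integer(object@nPhotons),
              if (object@converged) "converged" else "NOT converged"))
})

# ---- LifetimeHistogram / PopulationModel -----------------------------------

#' Histogram of per-molecule lifetimes for one dataset
#'
#' @slot binEdges uniform bin edges (ns), starting at 0.
#' @slot counts molecule counts per bin.
#' @slot label dataset label, e.g. "ATTO643_12bp".
#' @exportClass LifetimeHistogram
setClass("LifetimeHistogram",
  slots = c(binEdges = "numeric", counts = "numeric", label = "character"))

setValidity("LifetimeHistogram", function(object) {
  if (length(object@binEdges) != length(object@counts) + 1L)
    return("length(binEdges) must be length(counts) + 1")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Gaussian-mixture decomposition of a lifetime histogram
#'
#' Sum-of-Gaussians least-squares fit to binned lifetime counts. Component
#' widths are box-constrained (default 0.05--0.5 ns); weights are normalized
#' component areas; components are sorted by ascending mean.
#'
#' @slot mean component means (ns), ascending.
#' @slot sigma component widths (ns), inside the box constraint.
#' @slot weight normalized component areas.
#' @slot amplitude fitted peak amplitudes (counts).
#' @slot aic Akaike Information Criterion, Neyman chi-square + `2*(3m)`.
#' @slot rss residual sum of squares.
#' @slot sigmaBounds the (lo, hi) width box used.
#' @slot pinnedSigma logical, width at a box bound.
#' @exportClass PopulationModel
setClass("PopulationModel",
  slots = c(mean = "numeric", sigma = "numeric", weight = "numeric",
            amplitude = "numeric", aic = "numeric", rss = "numeric",
            sigmaBounds = "numeric", pinnedSigma = "logical"))

setValidity("PopulationModel", function(object) {
  m <- length(object@mean)
  if (length(object@sigma) != m || length(object@weight) != m)
    return("mean, sigma and weight must have equal length")
  if (any(object@weight <= 0)) return("weights must be positive")
  if (is.unsorted(object@mean)) return("means must be sorted ascending")
  if (any(object@sigma < object@sigmaBounds[1] - 1e-9) ||
      any(object@sigma > object@sigmaBounds[2] + 1e-9))
    return("sigmas must respect sigmaBounds")
  TRUE
})

#' @describeIn PopulationModel number of mixture components.
#' @param x a `PopulationModel`.
#' @export
nComponents <- function(x) length(x@mean)

#' @export
componentTable <- function(x) {
  data.frame(mean_ns = x@mean, sigma_ns = x@sigma, weight = x@weight,
             amplitude = x@amplitude, pinned_sigma = x@pinnedSigma)
}

setMethod("show", "PopulationModel", function(object) {
  cat("PopulationModel with", length(object@mean), "component(s); AIC =",
      round(object@aic, 2), "\n")
  print(round(componentTable(object)[, 1:3], 4))
})

#' Physical labels for mixture components
#'
#' @slot unquenched index of the unquenched component (integer(0) if absent).
#' @slot perpendicular index of the less-quenched (perpendicular-duplex)
#'   component (integer(0) if absent).
#' @slot tilted indices of the remaining, more strongly quenched components.
#' @exportClass PopulationAssignment
setClass("PopulationAssignment",
  slots = c(unquenched = "integer", perpendicular = "integer", tilted = "integer"))

setMethod("show", "PopulationAssignment", function(object) {
  fmt <- function(i) if (length(i)) paste(i, collapse = ",") else "absent"
  cat("PopulationAssignment: unquenched =", fmt(object@unquenched),
      "| perpendicular =", fmt(object@perpendicular),
      "| tilted =", fmt(object@tilted), "\n")
})

# ---- ScalingFit -------------------------------------------------------------

#' Distance-law fit result
#'
#' One-parameter least-squares fit of eta = 1/(1 + (d/d0)^n) with fixed
#' exponent n.
#'
#' @slot exponent the fixed exponent n.
#' @slot d0 characteristic 50%-efficiency distance (nm).
#' @slot d0Se standard error of d0 (nm).
#' @slot ssr sum of squared residuals.
#' @slot nPoints number of (d, eta) points fitted.
#' @slot weighted TRUE for inverse-variance weighting.
#' @slot atBound TRUE when d0 finished at the search bounds.
#' @slot nonDiscriminating TRUE when fewer than 3 points were available.
#' @exportClass ScalingFit
setClass("ScalingFit",
  slots = c(exponent = "numeric", d0 = "numeric", d0Se = "numeric",
            ssr = "numeric", nPoints = "numeric", weighted = "logical",
            atBound = "logical", nonDiscriminating = "logical"))

setValidity("ScalingFit", function(object) {
  if (object@d0 <= 0) return("d0 must be positive")
  if (object@ssr < 0) return("ssr must be non-negative")
  TRUE
})

#' @export
characteristicDistance <- function(x) x@d0

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: eta = 1/(1+(d/d0)^%g), d0 = %.4g +/- %.2g nm, SSR = %.4g (%d points)%s\n",
              object@exponent, object@d0, object@d0Se, object@ssr,
              as.integer(object@nPoints),
              if (object@nonDiscriminating) " [non-discriminating]" else ""))
})

# ---- TrajectoryFrameSet / DuplexGeometry -----------------------------------

#' Coarse-grained duplex-on-nanotube trajectory
#'
#' Multi-frame pseudo-atom coordinates (nm) with a group map assigning each
#' atom to the SWCNT lattice, the capture strand, the complementary strand or
#' the anchor, a base-pair index for duplex atoms, and a tip flag marking the
#' 5'-terminal nucleotide of the complementary strand.
#'
#' @slot frames list of numeric matrices (nAtoms x 3), coordinates in nm.
#' @slot groups data.frame with columns `atom_index` (0-based), `group`
#'   (SWCNT/capture/complement/anchor), `bp_index` (-1 for non-duplex atoms)
#'   and `tip` (0/1).
#' @slot cylinderRadius nominal SWCNT radius (nm); NA when unknown.
#' @slot nBp duplex length in base pairs; NA when unknown.
#' @exportClass TrajectoryFrameSet
setClass("TrajectoryFrameSet",
  slots = c(frames = "list", groups = "data.frame",
            cylinderRadius = "numeric", nBp = "numeric"))

setValidity("TrajectoryFrameSet", function(object) {
  msg <- character()
  need <- c("atom_index", "group", "bp_index", "tip")
  if (!all(need %in% names(object@groups)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  na <- nrow(object@groups)
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L)
      return(sprintf("frame %d is not an nAtoms x 3 matrix", i))
    if (nrow(f) != na)
      return(sprintf("frame %d has %d atoms but the group map has %d", i, nrow(f), na))
  }
  if (!any(object@groups$group == "SWCNT"))
    msg <- c(msg, "at least one SWCNT atom is required")
  if (sum(object@groups$tip == 1) < 1)
    msg <- c(msg, "the 5'-tip nucleotide must be flagged in the group map")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrajectoryFrameSet number of frames.
#' @param x a `TrajectoryFrameSet`.
#' @export
nFrames <- function(x) length(x@frames)

#' @export
frameCoords <- function(x, i) x@frames[[i]]

#' @export
groupMap <- function(x) x@groups

setMethod("show", "TrajectoryFrameSet", function(object) {
  cat("TrajectoryFrameSet:", length(object@frames), "frame(s),",
      nrow(object@groups), "pseudo-atoms (",
      sum(object@groups$group == "SWCNT"), "SWCNT,",
      sum(object@groups$group %in% c("capture", "complement")), "duplex )\n")
})

#' Per-frame duplex geometry series
#'
#' @slot angleDeg per-frame tilt angle between duplex axis and tube axis
#'   (degrees, in `[0, 180]`).
#' @slot tipDistanceNm per-frame distance from the 5'-tip nucleotide centroid
#'   to the nearest SWCNT atom (nm).
#' @slot summary list of summary statistics (filled by [summarizeGeometry()]).
#' @exportClass DuplexGeometry
setClass("DuplexGeometry",
  slots = c(angleDeg = "numeric", tipDistanceNm = "numeric", summary = "list"))

setValidity("DuplexGeometry", function(object) {
  if (length(object@angleDeg) != length(object@tipDistanceNm))
    return("angle and distance series must have equal length")
  if (length(object@angleDeg) &&
      (any(object@angleDeg < 0) || any(object@angleDeg > 180)))
    return("angles must lie in [0, 180] degrees")
  if (length(object@tipDistanceNm) && any(object@tipDistanceNm < 0))
    return("distances must be non-negative")
  TRUE
})

#' @export
tiltSeries <- function(x) x@angleDeg

#' @export
tipDistanceSeries <- function(x) x@tipDistanceNm

setMethod("show", "DuplexGeometry", function(object) {
  cat(sprintf("DuplexGeometry: %d frames; angle %.1f deg (mean), tip distance %.3g nm (mean)\n",
              length(object@angleDeg), mean(object@angleDeg),
              mean(object@tipDistanceNm)))
})
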