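#' Principal axis of the SWCNT lattice
#'
#' The tube axis is the principal eigenvector of the SWCNT atom coordinate
#' covariance. Its sign is fixed so that the anchor-strand centroid projects
#' on the negative side of the SWCNT centroid: tilt angles above 90 degrees
#' then mean "tilted toward the anchor", below 90 "toward the overhang".
#'
#' @param frame nAtoms x 3 coordinate matrix (nm).
#' @param swcntIdx row indices of SWCNT atoms (>= 10).
#' @param anchorIdx row indices of anchor atoms (may be empty; the sign then
#'   defaults to a positive largest coordinate component).
#' @return unit 3-vector.
#' @export
tubeAxis <- function(frame, swcntIdx, anchorIdx = integer(0)) {
  .stopIfNot(length(swcntIdx) >= 10, "need >= 10 SWCNT atoms (got %d)",
             length(swcntIdx))
  xyz <- frame[swcntIdx, , drop = FALSE]
  cv <- stats::cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  .stopIfNot(ev$values[1] > 1e-12 && ev$values[1] > 1e-6 * sum(ev$values),
             "degenerate SWCNT covariance: cannot define a tube axis")
  ax <- ev$vectors[, 1]
  if (length(anchorIdx)) {
    proj <- sum((colMeans(frame[anchorIdx, , drop = FALSE]) - colMeans(xyz)) * ax)
    if (proj > 0) ax <- -ax
  } else if (ax[which.max(abs(ax))] < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Principal axis of the duplex
#'
#' Line fit through the per-base-pair centroids (robust to end fraying),
#' oriented from the lowest base-pair index (SWCNT-proximal) to the highest
#' (tip).
#'
#' @param frame nAtoms x 3 coordinate matrix.
#' @param duplexIdx row indices of duplex (capture + complement) atoms.
#' @param bpIndex base-pair index for each duplex atom.
#' @return unit 3-vector.
#' @export
duplexAxis <- function(frame, duplexIdx, bpIndex) {
  .stopIfNot(length(duplexIdx) == length(bpIndex),
             "duplexIdx and bpIndex must have equal length")
  bps <- sort(unique(bpIndex))
  .stopIfNot(length(bps) >= 2, "need >= 2 base-pair groups (got %d)", length(bps))
  cen <- t(vapply(bps, function(b)
    colMeans(frame[duplexIdx[bpIndex == b], , drop = FALSE]), numeric(3)))
  cc <- sweep(cen, 2, colMeans(cen))
  ax <- svd(cc)$v[, 1]
  if (sum((cen[nrow(cen), ] - cen[1, ]) * ax) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Tilt angle between duplex and tube axis
#'
#' `theta = acos(a . b)` in degrees; 90 degrees is the perpendicular
#' orientation.
#'
#' @param axis1,axis2 unit 3-vectors (tube axis, duplex axis).
#' @return angle in degrees, in `[0, 180]`.
#' @export
tiltAngle <- function(axis1, axis2) {
  dp <- sum(axis1 * axis2) / sqrt(sum(axis1^2) * sum(axis2^2))
  acos(pmin(pmax(dp, -1), 1)) * 180 / pi
}

#' Distance from the 5'-tip nucleotide to the SWCNT surface
#'
#' Minimum Euclidean distance between the centroid of the flagged
#' 5'-terminal nucleotide's pseudo-atoms and any SWCNT atom — the "nearest
#' point on the surface" convention, robust to non-ideal tube geometries.
#'
#' @param frame nAtoms x 3 coordinate matrix.
#' @param tipIdx row indices of the tip nucleotide's atoms.
#' @param swcntIdx row indices of SWCNT atoms.
#' @return distance in nm.
#' @export
tipSurfaceDistance <- function(frame, tipIdx, swcntIdx) {
  .stopIfNot(length(tipIdx) >= 1, "tip atoms must be flagged")
  .stopIfNot(length(swcntIdx) >= 1, "SWCNT atoms required")
  tip <- colMeans(frame[tipIdx, , drop = FALSE])
  dif <- sweep(frame[swcntIdx, , drop = FALSE], 2, tip)
  sqrt(min(rowSums(dif^2)))
}

#' Expected duplex length from the helical rise
#'
#' @param nBp number of base pairs, >= 1.
#' @param rise rise per base pair (nm/bp), default 0.34 for B-DNA.
#' @return `nBp * rise` in nm (12 bp -> 4.08 nm).
#' @export
expectedDuplexLength <- function(nBp, rise = 0.34) {
  .stopIfNot(all(nBp >= 1), "nBp must be >= 1")
  nBp * rise
}

#' Per-frame tilt and tip-distance series of a trajectory
#'
#' @param traj a [TrajectoryFrameSet-class].
#' @return a [DuplexGeometry-class] (summary slot empty; see
#'   [summarizeGeometry()]).
#' @export
analyzeTrajectory <- function(traj) {
  g <- traj@groups
  sw <- which(g$group == "SWCNT")
  an <- which(g$group == "anchor")
  dup <- which(g$group %in% c("capture", "complement"))
  tip <- which(g$tip == 1)
  nF <- length(traj@frames)
  ang <- dist <- numeric(nF)
  for (f in seq_len(nF)) {
    fr <- traj@frames[[f]]
    ta <- tubeAxis(fr, sw, an)
    da <- duplexAxis(fr, dup, g$bp_index[dup])
    ang[f] <- tiltAngle(ta, da)
    dist[f] <- tipSurfaceDistance(fr, tip, sw)
  }
  new("DuplexGeometry", angleDeg = ang, tipDistanceNm = dist, summary = list())
}

#' Summary statistics and angle-distance correlation
#'
#' Mean, median and 5th/95th percentiles of both series, plus the Pearson
#' correlation between the tilt deviation from perpendicular, `|theta - 90|`,
#' and the tip-to-surface distance. Tilting lowers the tip, so the expected
#' sign is negative. The correlation is `NA` for constant series.
#'
#' @param geom a [DuplexGeometry-class] with >= 10 frames.
#' @return the same object with its `summary` slot filled: per-series
#'   `mean`, `median`, `p05`, `p95`, and `tilt_distance_correlation`.
#' @export
summarizeGeometry <- function(geom) {
  .stopIfNot(length(geom@angleDeg) >= 10, "need >= 10 frames (got %d)",
             length(geom@angleDeg))
  stat <- function(x) list(mean = mean(x), median = stats::median(x),
                           p05 = unname(stats::quantile(x, 0.05)),
                           p95 = unname(stats::quantile(x, 0.95)))
  dev <- abs(geom@angleDeg - 90)
  corr <- if (stats::sd(dev) > 0 && stats::sd(geom@tipDistanceNm) > 0)
    stats::cor(dev, geom@tipDistanceNm) else NA_real_
  geom@summary <- list(angle = stat(geom@angleDeg),
                       tip_distance = stat(geom@tipDistanceNm),
                       tilt_distance_correlation = corr)
  geom
}
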