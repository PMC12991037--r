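#' Bin a photon stream into an intensity time trace
#'
#' @param stream a [PhotonStream-class].
#' @param binWidth bin width in seconds (default 10 ms).
#' @return an [IntensityTrace-class]. The last partial bin is dropped.
#' @export
binTrace <- function(stream, binWidth = 0.01) {
  .stopIfNot(binWidth > 0, "binWidth must be positive (got %g)", binWidth)
  t <- stream@macroTime
  if (!length(t)) {
    warning("empty photon stream; returning a zero-count trace")
    return(new("IntensityTrace", binEdges = c(0, binWidth), counts = 0))
  }
  nBins <- floor(max(t) / binWidth)
  if (nBins < 1L) {
    # stream shorter than one bin: single bin covering it
    return(new("IntensityTrace", binEdges = c(0, binWidth),
               counts = sum(t < binWidth)))
  }
  edges <- seq(0, nBins * binWidth, by = binWidth)
  idx <- floor(t / binWidth) + 1L
  counts <- tabulate(idx[idx <= nBins], nbins = nBins)
  new("IntensityTrace", binEdges = edges, counts = as.numeric(counts))
}

# Poisson segment log-likelihood (up to data-only constants): C*log(C/L).
.segLL <- function(C, L) ifelse(C > 0, C * log(C / L), 0)

#' Detect intensity change points by Poisson binary segmentation
#'
#' Recursively splits the trace at the point maximizing the two-segment
#' Poisson log-likelihood gain over the one-segment model, accepting splits
#' while the gain exceeds `penalty`. The default penalty `3 * log(nBins)` is
#' BIC-like and calibrated for single-molecule photobleaching traces.
#'
#' @param trace an [IntensityTrace-class].
#' @param penalty log-likelihood gain threshold.
#' @param minSegment minimum segment length in bins.
#' @return sorted integer vector of change points; change point `s` means the
#'   rate changes between bins `s` and `s + 1`.
#' @export
detectBleachSteps <- function(trace, penalty = NULL, minSegment = 2L) {
  counts <- trace@counts
  n <- length(counts)
  .stopIfNot(n >= 1L, "trace must be non-empty")
  if (is.null(penalty)) penalty <- 3 * log(max(n, 2L))
  S <- c(0, cumsum(counts))
  cps <- integer(0)

  splitSeg <- function(i, j) {
    if (j - i + 1L < 2L * minSegment) return(invisible(NULL))
    s <- seq(i + minSegment - 1L, j - minSegment)
    if (!length(s)) return(invisible(NULL))
    cl <- S[s + 1L] - S[i]
    cr <- S[j + 1L] - S[s + 1L]
    gain <- .segLL(cl, s - i + 1L) + .segLL(cr, j - s) -
      .segLL(S[j + 1L] - S[i], j - i + 1L)
    k <- which.max(gain)
    if (gain[k] > penalty) {
      sp <- s[k]
      cps <<- c(cps, sp)
      splitSeg(i, sp)
      splitSeg(sp + 1L, j)
    }
    invisible(NULL)
  }
  splitSeg(1L, n)
  sort(cps)
}

#' Classify photobleaching steps in a segmented trace
#'
#' Counts downward rate steps and locates the photobleaching time. A molecule
#' is considered fully bleached when the final segment's mean count is
#' consistent with background; only then are downward steps counted (a trace
#' still bright at the end has no complete bleaching record and gets
#' `n_steps = 0`). The bleach time is the start of the first segment from
#' which the trace stays at background.
#'
#' A bleach step falling inside a bin leaves a one-to-two-bin segment at an
#' intermediate count level; such short segments are transition artifacts,
#' not photophysical levels, and are merged into the following segment
#' before steps are counted.
#'
#' @param trace an [IntensityTrace-class].
#' @param changepoints output of [detectBleachSteps()].
#' @param background expected background counts per bin; when `NULL` it is
#'   estimated as the smallest segment mean.
#' @param minLevelBins segments shorter than this are treated as transition
#'   artifacts (default 3 bins).
#' @return list with `nSteps`, `bleachTime` (s, `NA` if never bleached),
#'   `segmentMeans`, `background`.
#' @export
classifyBleachSteps <- function(trace, changepoints, background = NULL,
                                minLevelBins = 3L) {
  counts <- trace@counts
  edges <- trace@binEdges
  bounds <- c(0L, changepoints, length(counts))
  # merge short intermediate segments into the preceding one (the first
  # segment, if short, merges forward), so the background tail stays pure
  repeat {
    len <- diff(bounds)
    short <- which(len < minLevelBins & len < sum(len))
    if (!length(short)) break
    drop <- if (short[1] == 1L) 2L else short[1]
    bounds <- bounds[-drop]
  }
  nSeg <- length(bounds) - 1L
  segMean <- segLen <- numeric(nSeg)
  for (k in seq_len(nSeg)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    segMean[k] <- mean(counts[idx])
    segLen[k] <- length(idx)
  }
  if (is.null(background)) background <- min(segMean)
  atBg <- segMean <= background + 3 * sqrt(pmax(background, 1e-9) / segLen) + 1e-9

  if (!atBg[nSeg] || nSeg == 1L)
    return(list(nSteps = 0L, bleachTime = NA_real_,
                segmentMeans = segMean, background = background))

  down <- which(diff(segMean) < 0)
  # first segment index from which the trace stays at background
  tail_bg <- which(rev(cumprod(rev(atBg))) == 1)[1]
  bleachTime <- edges[bounds[tail_bg] + 1L]
  list(nSteps = length(down), bleachTime = bleachTime,
       segmentMeans = segMean, background = background)
}

#' Build a TCSPC decay histogram from a photon stream
#'
#' @param stream a [PhotonStream-class].
#' @param nBins number of uniform micro-time bins (>= 32, default 256).
#' @param bleachTime photobleaching time (s); with `postBleachExclusion` only
#'   photons arriving before it are histogrammed.
#' @param postBleachExclusion logical.
#' @return a [DecayCurve-class].
#' @export
buildDecay <- function(stream, nBins = 256L, bleachTime = NA_real_,
                       postBleachExclusion = TRUE) {
  .stopIfNot(nBins >= 32L, "nBins must be >= 32 (got %d)", nBins)
  micro <- stream@microTime
  if (postBleachExclusion && !is.na(bleachTime))
    micro <- micro[stream@macroTime < bleachTime]
  w <- stream@tcspcWindow
  edges <- seq(0, w, length.out = nBins + 1L)
  idx <- pmin(floor(micro / (w / nBins)) + 1L, nBins)
  counts <- tabulate(idx, nbins = nBins)
  new("DecayCurve", binEdges = edges, counts = as.numeric(counts),
      tcspcWindow = w, excitationPeriod = stream@excitationPeriod)
}

.decayLsq <- function(par, edges, counts, sigma, period) {
  tau <- exp(par[1]); b <- stats::plogis(par[2]); t0 <- par[3]
  mu <- sum(counts) * .decayBinProbs(edges, tau, sigma, t0, b, period)
  sum((counts - mu)^2 / pmax(counts, 1))
}

#' Fit a monoexponential decay with IRF reconvolution
#'
#' Fits the per-bin model `N * ((1-b) * (Exp(tau) conv Gaussian(irfSigma)),
#' wrapped on the excitation period) + b * flat)` to a TCSPC histogram. The
#' convolution has the analytic exponentially-modified-Gaussian form, so bin
#' contents are exact CDF differences (no discretization bias at short
#' lifetimes). `"mle"` maximizes the multinomial (photon-counting) likelihood
#' over `(tau, b, t0)`; `"lsq"` minimizes Neyman-weighted squared residuals.
#' The lifetime standard error comes from the observed-information diagonal.
#'
#' @param decay a [DecayCurve-class].
#' @param irfSigma Gaussian IRF width (ns), fixed during the fit.
#' @param fitMode `"mle"` (default) or `"lsq"`.
#' @param minPhotons minimum photons required (default 100); below it the fit
#'   is returned unconverged.
#' @param tauBounds search box for tau (ns).
#' @param t0Init optional IRF offset start value.
#' @return a [LifetimeFit-class].
#' @export
fitMonoexponential <- function(decay, irfSigma = 0.1,
                               fitMode = c("mle", "lsq"),
                               minPhotons = 100L,
                               tauBounds = c(0.02, 2 * decay@tcspcWindow),
                               t0Init = NULL) {
  fitMode <- match.arg(fitMode)
  .stopIfNot(irfSigma >= 0, "irfSigma must be non-negative (got %g)", irfSigma)
  edges <- decay@binEdges
  counts <- decay@counts
  period <- decay@excitationPeriod
  N <- sum(counts)

  failFit <- function() new("LifetimeFit", tau = tauBounds[1], tauSe = Inf,
                            backgroundFraction = 1, irfSigma = irfSigma,
                            t0 = 0, logLik = -Inf, nPhotons = N,
                            converged = FALSE, pinned = FALSE, fitMode = fitMode)
  if (N < minPhotons) return(failFit())

  mids <- (edges[-1] + edges[-length(edges)]) / 2
  if (is.null(t0Init)) t0Init <- max(mids[which.max(counts)] - irfSigma, 0)
  after <- mids > t0Init
  tauInit <- sum(counts[after] * (mids[after] - t0Init)) / max(sum(counts[after]), 1)
  tauInit <- min(max(tauInit, 1.2 * tauBounds[1]), 0.9 * tauBounds[2])

  lower <- c(log(tauBounds[1]), stats::qlogis(1e-6), 0)
  upper <- c(log(tauBounds[2]), stats::qlogis(1 - 1e-6), decay@tcspcWindow)

  if (fitMode == "mle") {
    # value and analytic gradient share one evaluation, cached on the
    # parameter vector so optim's separate fn/gr calls cost one pass
    cache <- new.env(parent = emptyenv())
    evalModel <- function(par) {
      if (!is.null(cache$par) && identical(cache$par, par)) return(cache$val)
      val <- .decayNllWithGrad(par, edges, counts, irfSigma, period)
      cache$par <- par; cache$val <- val
      val
    }
    fn <- function(par, ...) evalModel(par)$value
    gr <- function(par, ...) evalModel(par)$gradient
  } else {
    fn <- function(par, ...) .decayLsq(par, edges, counts, irfSigma, period)
    gr <- NULL
  }
  obj <- fn

  runOpt <- function(tini) tryCatch(
    stats::optim(c(log(tini), stats::qlogis(0.05), t0Init), fn, gr,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  best <- runOpt(tauInit)
  # fall back to dispersed starts only when the first attempt fails or pins
  if (is.null(best) || best$convergence != 0 ||
      best$par[1] <= lower[1] + 1e-6 || best$par[1] >= upper[1] - 1e-6) {
    for (tini in c(tauInit / 3, tauInit * 3)) {
      fit <- runOpt(min(max(tini, 1.2 * tauBounds[1]), 0.9 * tauBounds[2]))
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) return(failFit())

  H <- tryCatch(stats::optimHess(best$par, fn, gr), error = function(e) NULL)
  tau <- exp(best$par[1]); b <- stats::plogis(best$par[2]); t0 <- best$par[3]

  tauSe <- Inf
  identifiable <- FALSE
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi) && is.finite(Hi[1, 1]) && Hi[1, 1] > 0) {
      scale <- if (fitMode == "mle") 1 else 2   # lsq objective ~ chi^2
      tauSe <- tau * sqrt(scale * Hi[1, 1])
      identifiable <- TRUE
    }
  }
  pinned <- best$par[1] <= lower[1] + 1e-6 || best$par[1] >= upper[1] - 1e-6
  converged <- best$convergence == 0 && identifiable && b < 0.95

  ll <- if (fitMode == "mle") -best$value else {
    p <- .decayBinProbs(edges, tau, irfSigma, t0, b, period)
    sum(counts * log(pmax(p, 1e-300)))
  }
  new("LifetimeFit", tau = tau, tauSe = tauSe, backgroundFraction = b,
      irfSigma = irfSigma, t0 = t0, logLik = ll, nPhotons = N,
      converged = converged, pinned = pinned, fitMode = fitMode)
}

#' Process one photon stream into a molecule record
#'
#' Runs the single-molecule chain: trace binning, change-point detection,
#' single-bleach-step classification, pre-bleach decay construction and
#' monoexponential fitting. A molecule is accepted when it shows exactly one
#' photobleaching step, has at least `minPhotons` pre-bleach photons and its
#' fit converged without pinning.
#'
#' @param stream a [PhotonStream-class].
#' @param traceBinWidth intensity-trace bin width (s).
#' @param nDecayBins micro-time bins for the decay histogram.
#' @param irfSigma IRF width (ns) passed to the fit.
#' @param minPhotons acceptance threshold on pre-bleach photons.
#' @param penalty change-point penalty (`NULL` = default).
#' @param background expected background counts per trace bin (`NULL` =
#'   estimated from the trace).
#' @param fitMode decay fit mode.
#' @return one-row data.frame: `molecule_id`, `n_steps`, `accepted`,
#'   `tau_ns`, `tau_se_ns`, `background_fraction`, `n_photons`,
#'   `bleach_time_s`, `reject_reason`.
#' @export
processMolecule <- function(stream, traceBinWidth = 0.01, nDecayBins = 256L,
                            irfSigma = 0.1, minPhotons = 100L,
                            penalty = NULL, background = NULL,
                            fitMode = "mle") {
  trace <- suppressWarnings(binTrace(stream, traceBinWidth))
  cps <- detectBleachSteps(trace, penalty = penalty)
  cls <- classifyBleachSteps(trace, cps, background = background)

  rec <- data.frame(molecule_id = stream@moleculeId, n_steps = cls$nSteps,
                    accepted = FALSE, tau_ns = NA_real_, tau_se_ns = NA_real_,
                    background_fraction = NA_real_, n_photons = NA_integer_,
                    bleach_time_s = cls$bleachTime,
                    reject_reason = NA_character_, stringsAsFactors = FALSE)
  if (cls$nSteps != 1L) {
    rec$reject_reason <- sprintf("n_steps=%d", cls$nSteps)
    return(rec)
  }
  decay <- buildDecay(stream, nBins = nDecayBins, bleachTime = cls$bleachTime)
  rec$n_photons <- sum(decay@counts)
  if (rec$n_photons < minPhotons) {
    rec$reject_reason <- "too_few_photons"
    return(rec)
  }
  fit <- fitMonoexponential(decay, irfSigma = irfSigma, fitMode = fitMode,
                            minPhotons = minPhotons)
  rec$tau_ns <- fit@tau
  rec$tau_se_ns <- fit@tauSe
  rec$background_fraction <- fit@backgroundFraction
  if (!fit@converged) rec$reject_reason <- "fit_not_converged"
  else if (fit@pinned) rec$reject_reason <- "tau_at_bound"
  else rec$accepted <- TRUE
  rec
}

#' Fit lifetimes for a list of photon streams
#'
#' @param streams list of [PhotonStream-class] objects.
#' @param ... passed to [processMolecule()].
#' @return data.frame with one row per molecule (see [processMolecule()]).
#' @export
fitLifetimes <- function(streams, ...) {
  .stopIfNot(length(streams) > 0, "no photon streams supplied")
  do.call(rbind, lapply(streams, processMolecule, ...))
}
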