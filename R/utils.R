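# Internal numerics shared across modules.

# CDF of t0 + Normal(0, sigma^2) + Exponential(mean tau): the
# exponentially-modified-Gaussian arrival-time model of a pulsed decay.
# Stable evaluation via log Phi for the exp term. sigma = 0 reduces to the
# shifted exponential CDF.
.exgaussCdf <- function(x, tau, sigma, t0) {
  xs <- x - t0
  if (sigma <= 0) {
    out <- 1 - exp(-pmax(xs, 0) / tau)
    out[xs < 0] <- 0
    return(out)
  }
  u <- xs / sigma
  h <- sigma^2 / (2 * tau^2) - xs / tau +
    stats::pnorm(u - sigma / tau, log.p = TRUE)
  out <- stats::pnorm(u) - exp(h)
  pmin(pmax(out, 0), 1)
}

# Probability mass of the wrapped decay model in each micro-time bin.
# The observed micro-time is (t0 + G + E) mod period, truncated to the
# TCSPC window; edges are bin edges in [0, window]. Wrap terms k = -1..nWrap
# cover both the negative Gaussian tail and slow decays spilling over
# several excitation periods; one vectorized CDF call over all wraps.
.wrappedBinProbs <- function(edges, tau, sigma, t0, period, nWrap = 3L) {
  ks <- -1L:nWrap
  xs <- rep(edges, times = length(ks)) + rep(ks * period, each = length(edges))
  Fh <- matrix(.exgaussCdf(xs, tau, sigma, t0), nrow = length(edges))
  p <- rowSums(Fh[-1L, , drop = FALSE] - Fh[-nrow(Fh), , drop = FALSE])
  pmax(p, 0)
}

# Full per-bin probabilities: decay mixed with a flat background over the
# window. Probabilities need not sum to 1 when window < period (photons in
# the dead part of the period are undetected); they are renormalized so the
# fit conditions on detection.
.decayBinProbs <- function(edges, tau, sigma, t0, b, period) {
  window <- edges[length(edges)] - edges[1]
  sig <- .wrappedBinProbs(edges, tau, sigma, t0, period)
  ssum <- sum(sig)
  if (ssum <= 0) return(rep(diff(edges)[1] / window, length(edges) - 1L))
  (1 - b) * sig / ssum + b * diff(edges) / window
}

# Multinomial negative log-likelihood of the wrapped-decay + flat-background
# model together with its analytic gradient in the fitting parameterization
# par = (log tau, logit b, t0). The EMG density and the derivative of its CDF
# share the exp(h) term, so value and gradient come from one pass.
.decayNllWithGrad <- function(par, edges, counts, sigma, period, nWrap = 3L) {
  tau <- exp(par[1]); b <- stats::plogis(par[2]); t0 <- par[3]
  nE <- length(edges)
  ks <- -1L:nWrap
  xs <- rep(edges, times = length(ks)) + rep(ks * period, each = nE) - t0

  if (sigma > 0) {
    u <- xs / sigma
    a <- u - sigma / tau
    logPhiA <- stats::pnorm(a, log.p = TRUE)
    h <- sigma^2 / (2 * tau^2) - xs / tau + logPhiA
    Eh <- exp(h)
    F <- stats::pnorm(u) - Eh
    mills <- exp(stats::dnorm(a, log = TRUE) - logPhiA)
    dhdtau <- -sigma^2 / tau^3 + xs / tau^2 + mills * sigma / tau^2
    dFdtau <- -Eh * dhdtau
    dFdt0 <- -Eh / tau                       # density f(x) = exp(h)/tau
  } else {
    pos <- xs > 0
    ex <- ifelse(pos, exp(-pmax(xs, 0) / tau), 0)
    F <- ifelse(pos, 1 - ex, 0)
    dFdtau <- ifelse(pos, -xs / tau^2 * ex, 0)
    dFdt0 <- -ex / tau * pos
  }

  sumDiff <- function(M) {
    M <- matrix(M, nrow = nE)
    rowSums(M[-1L, , drop = FALSE] - M[-nE, , drop = FALSE])
  }
  s <- pmax(sumDiff(F), 0)
  dsTau <- sumDiff(dFdtau)
  dsT0 <- sumDiff(dFdt0)
  S <- sum(s)
  if (S <= 0) return(list(value = Inf, gradient = c(0, 0, 0)))
  w <- diff(edges) / (edges[nE] - edges[1])

  p <- (1 - b) * s / S + b * w
  p <- pmax(p, 1e-12)
  nll <- -sum(counts * log(p))

  dpTau <- (1 - b) * (dsTau * S - s * sum(dsTau)) / S^2
  dpT0 <- (1 - b) * (dsT0 * S - s * sum(dsT0)) / S^2
  dpB <- -s / S + w
  cp <- counts / p
  grad <- c(-sum(cp * dpTau) * tau,            # d/d log tau
            -sum(cp * dpB) * b * (1 - b),      # d/d logit b
            -sum(cp * dpT0))
  list(value = nll, gradient = grad)
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Truncated-normal sampler by rejection (bounds far from the mean are cheap
# for every use in this package).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
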