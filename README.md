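# cnet

Single-molecule analysis of distance-dependent energy transfer from organic
fluorophores to single-walled carbon nanotubes (CNET: carbon nanotube energy
transfer).

## The problem

SWCNTs are 1D excitonic quenchers: a dye held near the tube surface loses
its excitation energy to the nanotube and its fluorescence lifetime drops.
When dyes are positioned at defined heights by DNA duplexes standing on the
tube (12–24 bp, 0.34 nm/bp), the per-molecule lifetime becomes a distance
ruler. This package turns raw single-molecule photon records into that
ruler's calibration:

* **photon streams → lifetimes** — intensity-trace change-point detection
  selects molecules with a single photobleaching step; pre-bleach photons
  form a TCSPC decay; a monoexponential model with analytic Gaussian-IRF
  reconvolution is fitted by Poisson maximum likelihood, τ ∈ 0.1–3.5 ns;
* **lifetimes → populations** — per-dataset histograms are decomposed into
  Gaussian subpopulations (widths constrained to 0.05–0.5 ns) with the
  component count chosen by AIC; components are labelled unquenched
  (τ ≈ τ₀, dye on glass), perpendicular (least-quenched duplex
  conformation) and tilted;
* **populations → distance law** — the perpendicular peak of each duplex
  length gives a quenching efficiency η = 1 − τ/τ₀ at distance
  d = (trajectory-mean tip height) + 1.1 nm (linker + dye), and
  η(d) = 1 / (1 + (d/d₀)ⁿ) is fitted for d₀ at fixed exponent, with
  n ∈ {3,4,5,6} compared by residual sum of squares. For a 1D acceptor
  n = 5: the package's `lineTransferRate()` integrates the point-to-line
  near-field rate and matches the analytic C·(3π/8)·d⁻⁵ law to 1e-6;
* **trajectory geometry** — duplex tilt angles versus the tube axis and
  5′-tip-to-surface distances from multi-frame XYZ trajectories, plus a
  Förster overlap-ratio calculator for comparing two dyes on the same
  acceptor.

A first-class synthetic-data module (`simulatePhotonStream()`,
`simulateCohort()`, `geometryForwardModel()`, `simulateTrajectory()`,
`makeToySpectra()`) generates every input with known ground truth, so the
whole chain is testable end to end without instrument data.

## Worked example

Five duplex systems at the trajectory-mean distances (plus the 1.1 nm
linker), fully synthetic cohorts of 100 molecules each:

```r
library(cnet)
systems <- data.frame(
  label = c("12bp", "15bp", "18bp", "20bp", "24bp"),
  n_bp  = c(12, 15, 18, 20, 24),
  d_nm  = c(4.6, 5.0, 5.8, 6.2, 7.7) + 1.1,
  tau0  = 3.5
)
out <- runPipeline(systems, cnetConfig(seed = 1L, mRange = 1:3),
                   simulation = list(nMolecules = 100))
out$quenching_points
#>   dataset d_nm   eta eta_sd
#> 1    12bp  5.7 0.779 0.0334
#> 2    15bp  6.1 0.720 0.0402
#> 3    18bp  6.9 0.592 0.0438
#> 4    20bp  7.3 0.512 0.0395
#> 5    24bp  8.8 0.300 0.0373
out$scaling_fits
#>   exponent d0_nm d0_se_nm       ssr rank non_discriminating
#> 1        3 7.670  0.33373 0.0184596    4              FALSE
#> 2        4 7.492  0.11577 0.0038618    2              FALSE
#> 3        5 7.392  0.01861 0.0001477    1              FALSE
#> 4        6 7.328  0.09352 0.0050040    3              FALSE
```

489 of 500 simulated molecules pass the single-step filter. The quenching
efficiency falls from 0.78 at 5.7 nm to 0.30 at 8.8 nm; the d⁻⁵ law
attains the smallest SSR and returns d₀ = 7.39 ± 0.02 nm, recovering the
generating characteristic distance (7.4 nm) within its standard error.
(A warning that the unquenched component is absent in one dataset means
the small dye-on-glass fraction was not resolved as its own peak there —
the quenching analysis uses the perpendicular peak and is unaffected.)

`out$manifest` records the seed, configuration, package version and
per-stage record counts; rerunning with the same configuration reproduces
all tables exactly.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/cnet-cli.R` (subcommands `simulate`, `fit-lifetimes`,
`fit-populations`, `fit-cnet`, `geometry`, `overlap`).

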