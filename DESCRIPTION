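Package: cnet
Title: Distance-Dependent Energy Transfer from Single Fluorophores to Carbon Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule carbon nanotube energy transfer
    (CNET) experiments in which organic dyes are held at defined distances from
    single-walled carbon nanotubes (SWCNTs) by DNA duplexes. Converts per-molecule
    photon streams (TCSPC macro/micro times) into fluorescence lifetimes via
    photobleaching-step selection and monoexponential maximum-likelihood fitting
    with instrument-response reconvolution; decomposes lifetime distributions into
    Gaussian subpopulations with AIC model selection; converts lifetimes to
    quenching efficiencies and fits the 1D-acceptor distance law
    eta = 1/(1 + (d/d0)^n); computes the point-to-line transfer-rate integral that
    grounds the d^-5 scaling and the Forster overlap ratio of two dyes; and
    analyses duplex-on-nanotube trajectory geometry (tilt angle, tip-to-surface
    distance). A synthetic-data module generates photon streams, lifetime cohorts,
    duplex-on-cylinder trajectories and toy spectra with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
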