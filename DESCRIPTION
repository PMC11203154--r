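Package: spikelft
Title: Lattice Field Theory Analysis of Binary Spike Rasters
Version: 0.1.0
Authors@R: person("spikelft", "developers", role = c("aut", "cre"),
    email = "spikelft@example.org")
Description: Tools for analysing binary spike rasters (neurons x time bins) as
    lattice field theories. Builds the activity kernel and its hypermatrix of
    observables (offsets, rates, space- and time-correlation matrices and
    their connected variants), evaluates a lattice action with potential,
    kinetic and input couplings, computes Gibbs averages and partition
    functions by exact enumeration or Metropolis sampling, reconstructs
    couplings and fields by inverse-Ising formulas (Callen, naive mean field,
    TAP, independent pair, Sessak-Monasson), coarse-grains kernels by binning
    and decimation including a planar multielectrode (Utah-96) electrode
    kernel, aligns repeated trials by overlap maximisation, analyses
    coupling-distribution scaling with population size, and relates principal
    component analysis to a purely potential lattice action. A synthetic
    module generates Gibbs-sampled, refractory-Bernoulli and columnar-lattice
    rasters plus jittered trial ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
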