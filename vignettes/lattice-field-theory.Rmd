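---
title: "Spike rasters as lattice field theories: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike rasters as lattice field theories: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelft)
```

## The model

A recording of $N$ neurons over $T$ clock-time bins is a binary kernel
$\Omega = \{\varphi_{i\alpha} \in \{0,1\}\}$. Space is discretised by the
neurons themselves; time is discretised by the refractory period, which sets
a natural clock $\tau \approx 1$ ms (the `tau_ms` metadata field, default
1). The spin representation $\sigma = 2\varphi - 1$ is informationally
equivalent but weighs coincidences differently: binary products detect joint
firing only, spin products detect agreement.

The package's statistical model is a Gibbs measure over kernels,
$\eta(\Omega) \propto \exp(-\lambda \mathcal{A}(\Omega))$, with the
two-body, "non-relativistic" action

$$\mathcal{A}(\Omega \mid A, B, I) =
  \sum_{ij} A_{ij} \sum_\alpha \varphi_{i\alpha}\varphi_{j\alpha}
+ \sum_{\alpha\beta} B_{\alpha\beta} \sum_i \varphi_{i\alpha}\varphi_{i\beta}
- \sum_{i\alpha} I_{i\alpha}\varphi_{i\alpha}.$$

Only equal-time neuron pairs and equal-neuron time pairs interact; this is
what makes the second-order observables — the space-correlation matrix
$\Phi = \Omega\Omega^\dagger/T$ and the joint-spike matrix
$\Pi = \Omega^\dagger\Omega/N$ — sufficient statistics of the quadratic
part, and what reduces the inverse problem from $(NT)^2$ to $NT(N+T)$
parameters (`reduce_nonrelativistic()`). $\lambda > 0$ plays the role of an
inverse Planck constant; $\lambda \to \infty$ is the classical
(least-action) limit, handled by `ground_state()` as exhaustive or annealed
search, never by evaluating overflowing exponentials.

Assumptions worth keeping in mind: binary (not Potts) cells; a rigid
two-body truncation (no three-point interactions); causality expressed only
through the support of $B$; trials modelled as exchangeable replicas.

### Sign conventions (deliberate choices)

Two sign conventions in this formalism are genuinely ambiguous in the
literature, and we fixed them as follows:

* **Input sign.** The input enters the action as $-I\cdot X$. This is the
  unique choice under which the input-only partition function factorises as
  $\prod 2\cosh(\lambda I_{i\alpha})$ (`input_partition()`), the input
  measure $\rho$ satisfies
  $G(A,B,I) = R(I)\,\langle e^{-\lambda\mathcal{A}(M|A,B)}\rangle_\rho$
  (verified by enumeration in the tests), and the Callen inversion reads
  $\lambda I_l = \mathrm{atanh}(m_l)$ with a *positive* field producing a
  *positive* magnetisation.
* **Lagrangian sign.** `lagrangian_split()` returns the per-bin potential
  $H(\alpha) = \sum_{ij} A_{ij}\sigma_{i\alpha}\sigma_{j\alpha}$ and
  kinetic $K(\alpha) = -N\sum_{\beta<\alpha} B_{\alpha\beta} q_{\alpha\beta}$
  with $L = -H + K$; the action is *minus* the summed Lagrangian
  (`action_from_lagrangian()` computes $\sum_\alpha (H - K)$). The
  alternative bookkeeping (absorbing the minus into $K$) breaks either the
  action identity or the constant-offset relation between the nearest-step
  overlap coupling $B_{\alpha,\alpha-1} = -B_0$ and the pulse-kernel form
  $\tfrac{1}{2}B_0\lVert\partial\sigma\rVert^2$; with our choice the two
  Lagrangians differ by exactly $B_0 N$ per bin, configuration-independent,
  as the tests assert.

Causality is stored as a full $T\times T$ matrix validated to be strictly
triangular in the "earlier bins only" orientation ($B_{\alpha\beta} \ne 0$
only for $\beta < \alpha$); the first bin simply has no kinetic
predecessor.

## Evaluating the theory

`partition_function()` and `gibbs_average()` have two backends:

* **Enumeration** over all $2^{NT}$ kernels, capped at $NT \le 20$
  (about $10^6$ states, vectorised through the mixed-space quadratic form
  `grand_coupling()`; a few seconds). All exactness tests (replica
  factorisation $G(A,0) = Z(A)^T$, the Gibbs bound
  $\Psi \le F(\zeta)$, the renormalized-partition identity) run in this
  mode.
* **Metropolis** single-site flips with random scan, written in C++ with a
  seeded `mt19937` stream so results are bit-reproducible and independent
  of R's RNG state. Defaults: 1000 burn-in sweeps, thinning by full sweeps,
  mandatory seed. `partition_function(mode = "mcmc")` uses thermodynamic
  integration of $\langle\mathcal{A}\rangle_\lambda$ over a 21-point
  $\lambda$-grid from 0 (where $\log G = NT\log 2$ exactly), with a
  trapezoid rule and propagated Monte-Carlo errors. Error bars on Gibbs
  averages use an autocorrelation-based effective sample size; they are
  honest to a factor of order one, not exact.

The Gibbs variational bound is exposed as `free_action_functional()` for
product test measures; equality holds exactly when the model itself
factorises, which the tests exploit.

## Inverse-Ising reconstruction

All inverters act on the grand covariance
$C_{ll'} = \langle\sigma_l\sigma_{l'}\rangle - m_l m_{l'}$ over the mixed
index $l = (\alpha-1)N + i$. The reconstructed couplings follow the
standard inverse-Ising convention ($F \to -C^{-1}$ as $m \to 0$); under our
action convention the ground truth of a model is $F = -\lambda W$
off-diagonal, with $W$ the symmetrised mixed-space coupling matrix.
Printed renderings of the TAP inversion vary and are easy to mangle
typographically; we implement the standard TAP solution of the quadratic
self-consistency,
$F_{ll'} = -2K_{ll'}/(1+\sqrt{1-8m_l m_{l'}K_{ll'}})$, $K = C^{-1}$, which
reduces exactly to naive mean field at $m=0$ (asserted in the tests);
negative discriminants are flagged per pair and fall back to naive mean
field. Empirically asymmetric covariances are symmetrised by averaging with
the transpose; near-singular covariances get a ridge of
$10^{-8}\,\mathrm{tr}(C)/L$ before inversion, flagged in the solution.
Sessak–Monasson subtracts the double-counted two-spin term from the
independent-pair closed form, so at $L = 2$ the two coincide — also
asserted, along with exactness of the independent-pair formula on true
two-spin systems and a $\ge 0.9$ coupling-recovery correlation from
$10^5$ exact-probability samples of a 10-spin model with couplings of
scale $0.3/\sqrt{N}$.

## Coarse-graining

`bin_renormalize()` implements the any-spike indicator per
$N_2 \times T_2$ block (the map used for 10 ms binning of 1 ms rasters:
the joint-spike matrix shrinks by $T_2^2 = 100$); `decimate()` keeps one
representative site per block (first site by default, offset
configurable). Shapes that do not factor are rejected by default;
`truncate` and `pad` policies are available and warn.

`effective_couplings()` records, per configuration, the block sums
$\hat A_{i_1 j_1 \alpha_1}(\Omega)$ and
$\hat B_{i_1\alpha_1\beta_1}(\Omega)$ that carry the fine action onto the
coarse variables. The split into a stationary coupling matrix plus
fluctuations is not unique; we define $\hat A$ as the mean of the block
sums **conditional on the coarse product being 1** (the only entries that
enter the coarse action). This choice makes $\hat A = A$ exactly for
$1\times1$ blocks, and leaves the renormalized partition identity
$$G(A,B) = \sum_{\hat\Omega}
  \exp[-\lambda \mathcal{A}(\hat\Omega|\hat A,\hat B)
       - \lambda\,\delta\mathcal{A}(\hat\Omega)]$$
exact for *any* stationary split, since the perturbation
$\delta\mathcal{A}$ absorbs the remainder by a log-sum over each coarse
configuration's preimage fibre; the tests verify this to $10^{-10}$ by
enumeration. Random-energy-model style approximations of the fluctuation
term are out of scope.

The electrode kernel models planar arrays: neurons are assigned to the
nearest recording site within a listening radius (default half the pitch;
Utah-96: $10\times10$ grid, 0.4 mm pitch, four silent corners, 96
channels), and a site is ON in a bin iff any assigned neuron fires. Because
both operations are per-cell ORs, the electrode kernel commutes with time
binning, which is asserted as a property.

## Trial ensembles and alignment

Trials are equal-$N$ kernels with a common analysis window cut from each
recording; integer shifts $\nu_k$ re-cut the windows
($\alpha \to \alpha + \nu_k$). Event alignment (e.g. on movement onset) is
the default workflow; norm-maximisation (`align_trials()`) maximises
$\lVert Q(\nu)\rVert_F^2$ of the trial-overlap matrix, exhaustively when
the search space has at most $10^4$ points and by seeded coordinate ascent
with random restarts (zero included as a start, so the returned norm never
drops below the zero-shift norm) otherwise. Note that the objective is
invariant under a *common* shift only up to window content: identical
trials pin the relative shifts, not the absolute ones. Ensemble averages
produce the mean kernel and the covariance corrections
$\delta C = \langle C\rangle - \langle M\rangle\langle M\rangle^\dagger/T$
(and $\delta Q$), which vanish identically for a single trial and match
the non-relativistic reduction of the grand covariance entry-by-entry.

## Coupling-scaling analysis

`generate_couplings()` draws $A_{ij} = (J_0 + J_{ij})\Lambda_{ij}/g$ with a
single stationary Gaussian $J_0$ per matrix (a per-pair option exists; the
once-per-matrix reading matches the word "stationary") and unit-variance
symmetric fluctuations, $g = N^\alpha$ in the exponent regime. The entry
standard deviation on the connected support thus scales as $N^{-\alpha}$:
exponent 1 is the fully connected normalisation, exponent 1/2 the
sub-linear-connectivity regime. `scaling_fit()` reports both Gaussian-ML
and raw-moment spreads (identical up to the $1/n$ vs $1/(n-1)$ divisor —
the histogram-fit route used with digitised figures is not reproducible
without the figure) and regresses $\log$ sd on $\log N$; recovery of both
exponents within two standard errors is part of the test suite.
`pca_action()` ties PCA into the same framework: the action equals minus
the top-$n$ eigenvalue sum of $\Omega\Omega^\dagger$ (checked against an
SVD oracle), the induced couplings are $-YY^\dagger$ with trace $-n$,
eigenvectors are ordered by descending eigenvalue with a
first-nonzero-positive sign convention, and time-domain PCA is the
transposed (purely kinetic) dual.

## What the synthetic generators do and do not establish

The generators emulate the statistical skeleton of cortical recordings: a
1 ms clock, Bernoulli firing with an absolute refractory period (default
rates a few percent per bin, refractory 4–5 bins, which reproduces the
near-diagonal suppression band in the time covariance and the renewal-rate
bias $p/(1+pr)$), minitube-like co-activation groups for the electrode
kernel, and rigid jitter plus salt-and-pepper flips for trial ensembles.
They do **not** emulate oscillations, firing-rate non-stationarity, spike
sorting errors, electrode drift, or realistic connectivity topology. A
green test therefore establishes correctness of the *operations* and
self-consistency of the *theory* on its stated world — not that the model
fits any particular biological dataset. The monkey/retina analyses that
motivated the framework require recordings this package does not ship.

## Numerical choices and degenerate inputs

* Lagged sums are truncated to valid pairs and normalised by $T-k$
  (unbiased per pair); per-lag counts and standard errors expose the
  divergence as $k \to T$. Lag-consistency between neuron-averaged
  autocorrelations and time overlaps is then an exact identity.
* Wasserstein distances pair sorted values directly for equal lengths and
  otherwise evaluate both right-continuous quantile functions on a
  `max(len)`-point midpoint grid.
* Saturated sites ($|m|=1$) make the Callen inversion fail loudly rather
  than clip; inverters clamp means only in the derived *field* estimates.
* Kernel entries are stored as integers; metadata (τ, alignment bin,
  labels) is carried in headers and never inferred from data.
* Bundle floats are written with 17 significant digits and guarded by md5
  checksums, so hypermatrix directories round-trip bit-faithfully.
* The neuron ordering θ is arbitrary by design; only a baseline-activity
  sorter (first 250 ms by default, ties by original index) is provided.

## Known limitations

Enumeration is exponential and capped; MCMC error bars are approximate;
the causal (time-sliced conditional) sampler coincides with the global
Gibbs measure only for nearest-step kinetic couplings with
configuration-independent normalisation, and both are provided without
privileging either; decimation effective couplings share the bin-map
bookkeeping (the representative-exclusion variant changes only the split,
not the exact identity); ergodicity "in distribution" is reported as
Wasserstein distances without a pass/fail threshold, since none is
established.
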