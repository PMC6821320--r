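---
title: "Methods: the four-step TEC scheme and its estimation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-step TEC scheme and its estimation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecKinetics)
```

## The model

A transcription elongation complex (TEC) poised one nucleotide before a
templated addition site is rapid-mixed with the substrate NTP. The
package models the ensuing reaction as a linear cascade of five states,

$$ I \underset{k_{inact}}{\overset{k_{act}}{\rightleftharpoons}} A
   \underset{k_{off}}{\overset{k_{on}[\mathrm{NTP}]}{\rightleftharpoons}}
   A{\cdot}N \overset{k_{inc}}{\longrightarrow} PRE
   \overset{k_{tra}}{\longrightarrow} POST $$

with units fixed package-wide: seconds, micromolar, rates in s^-1 and
uM^-1 s^-1. The assumptions baked into this scheme:

- **Pseudo-first-order substrate.** The NTP is in at least 12.5-fold
  excess over the TEC in every supported design (final 0.1 uM TEC
  against 1.25-250 uM NTP), so `[NTP]` is treated as a constant and
  binding is first-order with rate `k_on * [NTP]`. Substrate depletion
  is deliberately out of scope.
- **A slow inactive fraction.** TEC preparations contain a minority
  population that adds nucleotides much more slowly than the main
  population. This is modeled as an inactive state `I` in slow,
  reversible exchange with the active state `A`. The initial split is
  its own parameter, `f_inactive0`, rather than being forced to the
  isomerization equilibrium `k_inact/(k_act + k_inact)`: the fraction
  and the exchange rates are conceptually distinct observables, and the
  reference parameter set keeps them mutually consistent (equilibrium
  0.09 vs `f_inactive0` = 0.10) without tying them. Nothing in the
  likelihood prevents a user from fixing one to the other.
- **Irreversible incorporation and translocation.** Phosphodiester bond
  formation is effectively irreversible under single-round conditions.
  Translocation is fit as a one-way step, so the fitted `k_tra` is an
  *apparent* rate: for a reversible hop observed through an absorbing
  readout, the fitted rate equals the sum of the forward and backward
  rates. A reversible pre/post variant is intentionally not offered.

The scheme is linear, so the occupancy vector evolves as
$x(t) = e^{Qt} x_0$ with `Q` the (tridiagonal) generator.

## Observables

- **HCl quench** stops all chemistry instantly: extended-RNA fraction
  `PRE + POST`.
- **EDTA quench** chelates the catalytic Mg^2+ and inactivates *free*
  NTP, but NTP already bound in the active site still partitions between
  incorporation and dissociation. The observable is
  `PRE + POST + p * AN` with `p = k_inc / (k_inc + k_off)`. The package
  applies this partition as an instantaneous rule rather than
  integrating the post-quench decay; the two are mathematically
  identical for the end-point observable (a test verifies this against
  explicit post-quench integration), and the partition form is what the
  pulse-chase treatment states. When `k_inc = k_off = 0` the bound state
  never drains and `p` is defined as 1. The EDTA signal dominates the
  HCl signal pointwise, with equality whenever `AN = 0` or `k_inc = 0`.
- **6-MI fluorescence.** The fluorescent guanine analog
  6-methyl-isoxanthopterin placed in the downstream DNA duplex is
  quenched by its neighboring base pairs in the initial *and* the
  pre-translocated complex, and brightens when translocation brings it
  to the duplex edge: signal `offset + scale * POST`. Raw stopped-flow
  intensities are instrument-scaled, so every fluorescence trace carries
  its own `scale` and `offset`. These are linear nuisance parameters and
  are profiled analytically (weighted least squares given the `POST`
  trace) inside every objective evaluation — the nonlinear optimizer
  never sees them. The bundled reference optics (`offset = 1`,
  `scale = 2`) encode the 3-fold fluorescence enhancement of a fully
  translocated uridine-extended TEC.
- **Equilibrium amplitude ratios.** `post_fraction_from_amplitudes()`
  estimates a test TEC's post-translocated fraction as the ratio of its
  fluorescence amplitude to a fully translocated reference. This assumes
  the pre-translocated state shares the *exact* baseline of the initial
  state; the measurements only establish that both are "quenched", so
  the function documents the assumption and flags (rather than clips)
  ratios above 1.

## Reference parameter sets

The generators default to rate sets describing single-round uridine
(and pseudouridine) incorporation by the *E. coli* RNA polymerase at
25 C. The anchors are the reported hallmarks of this system: an
approximately 10% inactive fraction exchanging more than an order of
magnitude more slowly than addition; a 2-fold larger association rate
for pseudouridine triphosphate with equal incorporation and
translocation rates; a fast guanosine-incorporation phase of ~14 s^-1
carrying 50-60% of the amplitude with a dispersed ~1 s^-1 slow phase;
and a >10-fold faster Gre-facilitated cleavage for the analog-extended
TEC. Magnitudes not printed anywhere (`k_on` = 1 uM^-1 s^-1, `k_off` =
70 s^-1, `k_inc` = 55 s^-1, `k_tra` = 200 s^-1) were chosen once as
field-typical values consistent with those anchors — moderate binding
affinity, incorporation at tens per second, translocation fast enough
to add only a small delay at saturating substrate — and are not tuned
thereafter. The slow-phase "rate" of the two-phase form is reported as
the reciprocal of the slow-phase *median* time, since a stretched
exponential has no single rate constant; `tau` alone is not comparable
across different `beta`.

The fluorescence concentration series is an 8-point geometric ladder
spanning 1.25-250 uM (step ~2.13): the nominal protocol mixes two-fold
NTP dilutions 1:1 with the TEC, and a geometric series spanning the
stated final endpoints is the closest self-consistent emulation.

## Numerics

- **Propagation.** The generator is tridiagonal with non-negative
  off-diagonals, hence similar to a symmetric matrix and real-spectral.
  The propagator uses an eigendecomposition (one factorization per
  trace, then a dense `5 x T` evaluation), verified at the largest
  requested time against a scaling-and-squaring matrix exponential; if
  the eigenbasis is ill-conditioned (near-defective rate coincidences)
  it falls back to `Matrix::expm()` per time point. Relative accuracy is
  well inside the 1e-8 contract; conservation holds to 1e-9 and small
  negative round-off (> -1e-12) is clipped to zero.
- **Stochastic cross-check.** `gillespie_oracle()` simulates the same
  chain as independent molecules with exponential holding times and
  jump-chain draws — no matrix exponentials anywhere — and reports
  binomial standard errors. The deterministic and stochastic routes are
  compared within 3 standard errors in the tests.
- **Global fit.** Rates are optimized on the log scale (they span five
  orders of magnitude) by bounded Levenberg-Marquardt
  (`minpack.lm::nls.lm`), multi-started (default 8 starts; the first at
  the user/start rate set, the rest from a seeded Latin hypercube over
  the log box). Restart ties (chi-square within 1e-9) resolve to the
  lowest restart index, making results deterministic given the seed.
  Default box bounds are wide (e.g. 1e-3 to 1e3 uM^-1 s^-1 for `k_on`,
  1e-3 to 0.6 for `f_inactive0`).
- **Weights.** When a trace carries no `sigma`, the default is a
  per-trace constant of 3% of that trace's signal range (floor 1e-3 of
  range), which weights heterogeneous traces roughly uniformly. Because
  no noise model is asserted for real instruments, absolute chi-square
  values are not meaningful across datasets; everything downstream uses
  threshold-*relative* chi-square only. Estimates are invariant to
  uniform sigma rescaling (chi-square rescales by the inverse square),
  and to trace ordering up to optimizer arithmetic.
- **Profile bounds.** For each floated parameter the profile is scanned
  by bisection in log space between the best fit and the box edge, with
  all other parameters re-optimized (warm-started) at every trial, up to
  60 evaluations per side and a relative bracket tolerance of 1e-3. The
  bound returned is the last *evaluated* point, so the reported
  chi-square at a non-clipped bound is within 1% of
  `threshold_factor * chi2_min` by construction; sides that never reach
  the threshold inside the box return the box edge with a `clipped`
  flag. `threshold_factor = 1` returns the degenerate point bound;
  values below 1 are rejected.
- **Phase fits.** The two-phase form is
  `A_fast(1 - e^{-k_fast t}) + A_slow(1 - e^{-(t/tau)^beta})` with the
  stretched exponential parameterized as `(t/tau)^beta` so `tau` keeps
  time units. The exponential term is *defined* as the faster phase,
  enforced via `k_fast = e^r / tau` with `r >= 0`. When the slow phase
  degenerates into the fast exponential (`beta -> 1`,
  `1/tau -> k_fast`) the amplitude split is unidentifiable; the tie is
  broken toward the exponential by merging the amplitudes whenever the
  merged single-exponential does not worsen the residual sum
  materially. Starting values are data-driven (fast rate from the
  earliest 20% of the rise, `tau` from the half-rise time) with a
  fixed-seed 4-point multistart. Constant traces are rejected as
  degenerate, except the all-zero cleavage course, which returns a
  flagged "no cleavage" result (`cleavable = 0`). Median times use the
  closed form `tau * log(2)^(1/beta)`.
- **Gel quantification.** Arrest ratios use raw counts; the 8-bit
  panel-wide scaling (minimum to 0, maximum to 255, one map per panel)
  is provided for display because its affine offset would bias ratios.
  The at-and-above denominator window is user-supplied — from the lane
  top down through the arrest site of the control lane — because no
  boundary rule is standard. No background
  subtraction is applied by default; an optional per-lane
  minimum-count subtraction is available. The method tolerates, but
  flags, ratios above 1 (unequal lane loadings are not corrected).

## What the synthetic data do and do not emulate

The generators are pure functions of (parameters, seed): byte-identical
on re-run, with sub-seeds derived deterministically for multi-trace
designs. They emulate trace shapes, concentration/time designs
(log-spaced 0.004-60 s quench grids, 0.002-10 s stopped-flow grids) and
Gaussian homoscedastic noise (default 2% of trace range). They do *not*
emulate instrument drift, photobleaching, mixing dead times, correlated
noise, gel smearing, or lane-loading error — so passing recovery tests
demonstrates the estimators are correct and well-conditioned under the
stated noise model, not that real instrument artifacts are handled.
Lane profiles are Gaussian bands (row-integrated, so band areas are
exact) on a constant baseline; electrophoretic mobility anomalies of
analog-containing RNA are an experimental observation, not modeled.

## Problem sizes

Defaults: 500 stopped-flow points per fluorescence trace, 50 quench
points per course, 10-trace datasets; the acceptance script runs this
full design. The test suite uses reduced designs (15-150 points per
trace, 2-5 concentrations, 2-3 restarts, 3-5 noise seeds, stochastic
ensembles of 6e4-1e5 molecules) chosen to exercise every contract at
comfortable margins while keeping the suite quick on a single CPU.

## Known limitations

- `k_tra` is identifiable only through the fluorescence/extension lag;
  designs without fluorescence traces leave it nearly unbounded above
  (the profile bound reports this honestly as a wide or clipped
  interval). Likewise `k_inact` is poorly bounded below in single-round
  designs.
- The EDTA partition rule assumes quenching of free NTP is instantaneous
  relative to `k_inc + k_off`.
- No Bayesian posteriors, no model selection between scheme variants,
  and no backtracking/elongation simulator: the scheme covers one
  addition-translocation round only.
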