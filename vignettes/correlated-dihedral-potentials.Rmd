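---
title: "Correlated dihedral potentials: models, choices and limitations"
author: "torsionPES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated dihedral potentials: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(torsionPES)
```

## The model landscape

torsionPES treats a molecule as rigid fragments connected by rotatable
bonds, so a conformation is fully described by its vector of `n_d` dihedral
angles (degrees, canonical range `[0, 360)`). Three energy models over that
space coexist in the package:

1. **Uncorrelated Fourier force field** — the standard four-term cosine
   series per torsion (amplitudes `V1..V4` in kcal/mol, phases `φ1..φ4` in
   degrees, alternating `+ − + −` signs in front of the cosines), summed over
   torsions plus a global offset.
2. **Uncorrelated tabulated force field** — the same additive structure, but
   each torsion profile is stored on its equally spaced scan grid and
   evaluated by periodic linear interpolation. Both are parameterized by
   `scan_parameterize()`: each torsion is scanned on an `n_s`-point grid with
   all other torsions clamped at a reference configuration, costing exactly
   `n_s * n_d` oracle evaluations for the scan.
3. **Energy network ensemble** — five feed-forward networks with logistic
   hidden units and a linear output, trained on random conformations and
   averaged. This is the only model whose hypothesis space contains
   angle–angle correlations.

The additive models are not strawmen: on a separable surface they are exact
up to fit/interpolation residual, and the test suite asserts this. Their
failure is structural, not statistical — a coupling term
`c · cos(m αi) cos(m' αj)` has zero mean along any one-angle scan line, so
no amount of scanning resolution recovers it. The benchmark
(`run_benchmark()`) shows both regimes on the same footing.

## Input encoding

Each configuration is encoded per dihedral as the raw angle in degrees
followed by `(sin kα, cos kα)` for `k ∈ {0.5, 1, 2, ..., 10}` — 23 features
per dihedral. Two choices deserve comment:

- The periodicity list is read as `{0.5} ∪ {1..10}` (11 values). It is a
  constructor argument (`feature_encoding()`), so other readings are one
  line away.
- The `k = 0.5` features are *not* 360°-periodic. They are made well defined
  by canonicalizing every angle into `[0, 360)` before encoding; the
  encoding of `360 − ε` therefore differs from that of `ε` in the
  half-angle cosine (which flips sign across the seam) while all integer-`k`
  features agree. Tests pin down exactly this semantics.
- Raw angles enter in degrees; the feature standardization (below) removes
  the scale mismatch with the bounded trigonometric features.

## Training protocol

`train_energy_ensemble()` standardizes features and targets using
training-split statistics only, then trains each member with Adam
(learning rate 1e-3, β₁ = 0.9, β₂ = 0.999), minibatches of 200, an L2
penalty of 1e-4 on weights, and early stopping on the 13% validation split:
training stops after 10 epochs without a relative improvement of 1e-4 in
validation loss, and the best epoch's weights are kept (the returned
validation loss equals the minimum of the recorded history — asserted in
tests). The split is 72/13/15 with validation/test sizes floor-rounded and
the remainder assigned to training; 150,000 samples give
108,000/19,500/22,500. Members share the split and the scalers and differ by
architecture (30×10, 100×10, 110×7, 60×30×10, 50×20×8) and seed
(`base_seed + member index`). The output unit is linear — energies are
unbounded above — and prediction is the de-standardized arithmetic mean of
the members.

The optimizer settings beyond the minibatch size, the standardization, the
L2 strength and the early-stopping patience are this package's defaults,
exposed in `training_control()`, not claims about any external reference
implementation.

The classifier ensemble (`train_classifier_ensemble()`) reuses the same
encoding, split protocol and optimizer with logistic outputs and the five
small architectures 30, 40, 50, 5×5, 10×3. Each member casts a binary vote
(output ≥/< 0.5); the reported probability is the mean of five votes, hence
the lattice {0, 0.2, 0.4, 0.6, 0.8, 1.0} and a never-tied majority. Votes
rather than averaged probabilities are used precisely because the 0.2-step
lattice is the published interface of such a gate. The positive class is
*low energy* — the class a Monte Carlo gate must not miss — so sensitivity
measures retained low-energy conformations.

## The synthetic surface

`make_pes()` builds the ground-truth oracle used throughout testing:

- per-dihedral cosine terms of orders 1–3 with amplitudes drawn from
  `U(0.5, 2)/m` kcal/mol and random phases — torsion barriers on the
  1 kcal/mol scale typical of conjugated linkages;
- pairwise couplings `c · cos(m αi − p) cos(m' αj − p')` with
  `|c| = coupling_strength · U(0.75, 1.25)`, random sign and random orders
  1–3; `coupling_strength = 0` yields an exactly separable surface;
- a global `amplitude_scale` multiplying every term. The benchmark default
  of 4 puts random-conformer energies on the tens-of-kcal/mol scale of
  semi-empirical conformer energies for branched aromatics, so that the
  46 kcal/mol (2 eV) classification threshold falls inside the energy
  distribution with both classes well populated;
- an energy zero set from the minimum over 10,000 random configurations,
  polished by BFGS descent from the 20 lowest sampled points. Pure random
  sampling leaves the true minimum ~0.01 kcal/mol below the sampled one;
  the polish makes the shifted surface nonnegative to ~1e-6.

The benchmark's default coupling graph is branched — a star on dihedral 1
plus one cross pair — because shared-hub torsions are where additive force
fields fail; `coupling_strength = 2` makes the coupling variance comparable
to the separable variance, which pins the best achievable additive-model
correlation near `r ≈ 0.7` a priori.

What the generator deliberately does **not** emulate: steep exchange
repulsion walls (energies here are bounded, smooth trigonometric
polynomials), bond-length/angle relaxation coupling into torsion profiles,
and any quantum-chemical realism. Passing tests therefore demonstrate that
the machinery recovers correlated structure a scan cannot, on surfaces of
realistic scale and smoothness — not that it reproduces any specific
molecule's chemistry. The geometry side is exercised separately by fixture
molecules (`make_fixture_molecule()`): invented rigid planar frames joined
by rotatable bonds, including a deliberately crowded branched hub whose
random rotations clash ~25% of the time under the 2.1 Å rule.

## Geometry and clash conventions

- Torsion sign: standard right-handed convention about `j → k`
  (`atan2((n1 × n2)·b̂2, n1·n2)`), mapped into `[0, 360)`; planar cis = 0,
  trans = 180. A fixed canonical range is required by the half-integer
  encoding features.
- `set_dihedral()` rotates the moving set — all atoms on the `l` side of the
  `j–k` bond, computed from the bond graph and validated to be a union of
  rigid fragments — about the `j–k` axis. Rigid-fragment internal distances
  are preserved to 1e-9 Å and the operation is reversible and commutative
  on tree-shaped rotatable-bond graphs (property-tested).
- Clash eligibility: a pair counts only if the atoms are in *different rigid
  fragments* and *≥ 4 bonds apart*. Intra-fragment and 1-2/1-3/1-4 distances
  are fixed or governed by a single torsion; flagging them would veto
  legitimate rotations. A single 2.1 Å threshold is used for all elements —
  no per-element radii — matching the simplest published practice; the
  comparison is strict (`< 2.1`), so a pair at exactly 2.1 Å is not a clash.

## Scan parameterization choices

- The scan grid for each torsion is aligned to pass through its reference
  angle, so the reference energy is read off the scan itself and the
  `n_s * n_d` call budget is exact. The default reference configuration is
  the per-dihedral argmin of a coarse 12-point pre-scan (an additional
  `12 * n_d` calls, counted separately in the model metadata).
- Offset anchoring: by default the assembled model reproduces the oracle at
  the reference configuration, which makes the fit *exact* (to least-squares
  or interpolation residual) for separable oracles on their absolute energy
  scale. The alternative — shifting so the model's scan-grid minimum is
  zero, the convention used when reference energies are themselves shifted
  to a global minimum — is available as `shift_min_zero = TRUE`. Anchoring
  was chosen as the default because a constant misfit would otherwise
  contaminate accuracy comparisons against an oracle whose own zero is only
  known to sampling tolerance.
- Fourier fitting is linear least squares in the 8-dimensional
  `{cos mφ, sin mφ}` basis, re-expressed as amplitudes and phases under the
  `+ − + −` sign pattern; a zero-amplitude term resolves its phase to 0.

## Monte Carlo

`run_mc()` is a single-molecule, single-temperature Metropolis chain:
proposals perturb one uniformly chosen dihedral by `U(−w, +w)` degrees
(`w = 30` by default), and acceptance uses
`min(1, exp(−ΔE / kB T))` with `kB = 0.0019872041 kcal/(mol·K)`. With a
gate, proposals classified high-energy are rejected before any energy
evaluation; the chain then targets the energy model restricted to the
classifier's low region — unbiased exactly when the gate's low region covers
the thermally accessible region, which the deep-low coverage check
(fraction of sub-23 kcal/mol conformations classified low ≈ 1) makes
plausible at 300–400 K. The proposal distribution is this package's choice;
annealing schedules and intermolecular terms are out of scope.

Validation of the sampler compares the long-run single-dihedral histogram
against the Boltzmann density on a 72-bin grid with a chi-square test at
α = 0.01. Two statistical details matter: raw Metropolis samples are
serially correlated, so the 10⁶-step chain is tested after a 10⁴-step
burn-in with thinning interval 100; and bin probabilities are integrated on
a 0.5° subgrid, because at n ≈ 10⁴ the midpoint approximation alone is
detectable.

## Problem sizes

The standard benchmark trains on 20,000 conformations of a 5-torsion
surface (14,400/2,600/3,000 split) with up to 200 epochs per member; the
regression pilot in the test suite uses 5,000 samples over 3 torsions at 60
epochs and the classifier pilot 8,000 samples at 100 epochs with the class
boundary at the median energy — the hardest placement. These sizes give
stable, seed-committed outcomes (ensemble r > 0.99 on the benchmark;
classifier accuracy ≈ 0.91–0.94) while keeping a full run on a single CPU
in the minutes range.

## Known limitations

- No gradients/forces: the models predict energies only, which suffices for
  Metropolis sampling but not for molecular dynamics.
- Rigid fragments: bond lengths and angles never relax, so torsion profiles
  absorb no back-bone strain.
- The uncorrelated force field implements torsion terms only — no
  Lennard-Jones or electrostatics — because it exists here as the additive
  baseline, not as a general-purpose force field.
- Ensemble training is plain R matrix code; it is fast enough for the
  documented sizes but makes no attempt at GPU-scale throughput.
- The classifier gate biases the chain wherever its low region clips
  thermally relevant conformations; use the ungated chain to measure that
  bias before production use.
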