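---
title: "Methods: coupling statistics and gating fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling statistics and gating fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvcoupling)
```

## The scientific setting

Voltage-gated potassium channels open when the S4 helix of each
voltage-sensor domain (VSD) moves outward upon depolarisation and that
movement is transmitted, via the S4S5 linker, to the S5–S6 pore domain (PD).
A small-molecule modulator lodged at the S4/S4S5/S5 interface can alter this
electro-mechanical coupling. Two complementary data streams inform on it:

* **replicate MD trajectories** of the channel with and without the ligand,
  from which correlated residue motion is read off dynamic cross-correlation
  matrices (DCCMs); and
* **voltage-clamp recordings**, from which the voltage dependence
  (Boltzmann $V_{1/2}$, slope $k$) and gating kinetics (biexponential
  $\tau_{fast}$, $\tau_{slow}$) of activation are fitted.

This package implements the full analysis layer for both streams plus
synthetic generators with analytically known ground truth, so that every
estimator can be validated end to end without the MD engine or the oocyte
rig.

## Trajectory statistics

**Superposition.** Every statistic is computed after removing rigid-body
motion: each frame is superposed onto a reference frame (the first, by
default) by the Kabsch algorithm — SVD of the 3×3 coordinate covariance with
the usual sign correction so the returned rotation is always proper
(determinant +1), even for mirror-degenerate inputs. The fit selection is
all Cα atoms by default and is configurable per call. No source protocol for
trajectory post-processing was available to copy, so whole-structure Cα
fitting — the common default in trajectory analysis tools — was adopted;
segment-local fits can be requested via `fit_segments` and will change
absolute RMSF/DCCM values, as they do in any analysis package.

**RMSD / RMSF.** RMSD is the per-frame root-mean-square deviation of a
selection from the reference frame; RMSF the per-atom RMS fluctuation about
the time-mean position, aggregated within residues as the RMS over the
residue's selected atoms. For isotropic Gaussian jitter with per-axis
standard deviation $\sigma$, $\mathrm{RMSF} = \sigma\sqrt{3}$; this closed
form anchors the estimator tests.

**DCCM.** The scalar (dot-product) definition over one representative atom
per residue (Cα):
$C_{ij} = \langle\Delta r_i\cdot\Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$.
Per-axis correlation matrices, PCA and mutual-information variants are out
of scope. The matrix is computed over the complete trajectory passed in;
time windowing is an explicit, separate step (`analysis_window`, inclusive
at both endpoints on the frame grid) so that snapshot bookkeeping — 120
frames per 30 ns run at 0.25 ns, 81 frames in the 10–30 ns window — is
auditable. Residues with zero displacement variance make the correlation
undefined; their rows/columns are returned as `NaN` with a warning rather
than silently coerced to 0, which would fabricate "no correlation".

**Replicate averaging and delta matrices.** Condition means are plain
entrywise arithmetic means over replicates (a Fisher-z option exists but is
off by default; the plain mean is the field's convention for averaged
DCCMs). The delta-DCCM is `mean_with - mean_without` with the diagonal
pinned to 0; segment-pair blocks (e.g. S4 × S6) are summarised by their
mean/min/max.

**Contacts.** A frame is "in contact" when the minimum heavy-atom distance
between ligand and residue is ≤ 4.0 Å (default), or when group centroids are
within 5.5 Å under the `"centroid"` criterion (an aromatic-ring proxy).
These cutoffs are standard literature values exposed as parameters, since no
authoritative thresholds were available for the interaction detector being
emulated; persistence percentages are therefore comparable only within one
cutoff choice. Hydrogens are excluded by element. Persistence is the
percentage of frames in contact; it is invariant to frame order and to
per-frame rigid motion because only intra-frame distances enter.

## The synthetic trajectory generator

The generator emulates the *statistical* structure of a production MD run,
not its physics: no force field, thermostat, or membrane. Its defaults are
the study design it stands in for — 120 frames at 0.25 ns (30 ns), replicate
counts 5 (with ligand) vs 3 (without), Cα-only tetrameric geometry with
chains A–D.

* **Displacements** are zero-mean Gaussian with per-axis σ = 0.5 Å, a
  typical equilibrated-backbone fluctuation scale (RMSF ≈ 0.87 Å).
* **Correlation blocks** are realised by a shared latent factor per block:
  per axis, $x_i = \sqrt{|\rho|}\,z + \sqrt{1-|\rho|}\,\varepsilon_i$, with
  the second segment's loading carrying $\mathrm{sign}(\rho)$. This makes
  the implied covariance positive semi-definite by construction and the
  target correlation exact analytically. Segments may not be shared between
  blocks (validated), which is what guarantees PSD without a numerical
  eigenvalue check.
* **Temporal smoothness** is an AR(1) filter
  $x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\,\eta_t$ (default φ = 0.5, a
  realistic frame-to-frame correlation at 0.25 ns sampling). The filter
  preserves the stationary marginal, hence the cross-residue correlation
  targets; it only shrinks the effective sample size by
  $(1+\phi)/(1-\phi)$, which is why recovery tests at exact tolerances
  switch it off and the φ = 0.5 check uses a widened tolerance.
* **Rigid-motion overlay** applies a random proper rotation and translation
  per frame after the displacements are drawn (so overlaid and plain runs
  share the same displacement stream and can be compared frame by frame).
  The superposition stage must remove it exactly; this is asserted at 1e-6.
* **Contact schedules** plant per-residue boolean contact series exactly: a
  one-atom-per-scheduled-residue ligand (chain X, resname RL3) tracks the
  target residue's Cα at 2 Å offset in contact frames and is displaced
  1000 Å away otherwise, so planted fractions are reproduced bit-exactly
  provided scheduled residues are farther apart than the cutoff.
* **Replicate seeds** are `base_seed + index` for the with-condition and
  `base_seed + n_with + index` for the without-condition. Offsetting the
  second condition keeps the two conditions on disjoint RNG streams: with
  shared seeds an identical-config null design would give a delta-DCCM of
  exactly zero and the null check would be vacuous.

What the generator does **not** emulate — and what passing tests therefore
do not show about real trajectories: anharmonic and multi-basin dynamics,
state transitions, solvent/membrane coupling, sequence-dependent
flexibility, and experimental artefacts such as periodic-boundary jumps.
Estimator correctness transfers; biological effect sizes do not.

A caveat the test design reflects: whole-structure superposition projects
out net translation/rotation, which slightly attenuates planted block
correlations when the correlated block is a sizeable fraction of the fitted
atoms. Recovery oracles therefore evaluate the estimator on raw
displacements (`superpose = FALSE`, the generator plants no rigid motion),
while invariance checks exercise the superposed path.

## Electrophysiology fits

All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`).

**G–V from tails.** The tail-current peak after each test pulse is
proportional to the open probability reached, because the tail driving force
and deactivation kinetics are the same for every test potential. The peak is
located after a 5 ms capacitive blanking window on a 25 ms boxcar-smoothed
magnitude (smoothing suppresses the upward bias of taking a maximum over
noisy samples); both windows are parameters. Values are normalised to the
+40 mV reference pulse.

**Boltzmann fit.** $G(V) = G_{max}/(1+\exp((V_{1/2}-V)/k))$, with the sign
convention $k > 0$ for depolarisation-activated channels (a flag flips it).
$G_{max}$ is a *free* nuisance parameter by default: at $V_{1/2} = -20$ mV
and $k = 12$ mV the open probability at the +40 mV reference is 0.9933, not
1, so a two-parameter fit of reference-normalised data is systematically
biased; the free scale removes that bias and the reported parameters remain
$V_{1/2}$ and $k$. `fluorescence_fit()` routes VCF dF/F curves through the
identical code path (asserted by test); no photobleach correction is applied
in this version.

**Biexponential kinetics.** Activation fits
$A_f(1-e^{-t/\tau_f}) + A_s(1-e^{-t/\tau_s}) + C$, deactivation the decaying
form. τ starting values are multi-started on a log-spaced grid over
[window/100, window] (all ordered pairs from a 5-point grid), with
amplitudes seeded by linear least squares given the trial taus. The
fast/slow labels are assigned by sorting the fitted taus. Degenerate inputs
are handled explicitly: a flat trace returns zero amplitudes with a
`degenerate` flag; a single-exponential input lands on a flat ridge of the
(A, τ) surface where many starts tie in residual, and among residual ties
(relative 1e-6, plus an absolute floor of 1e-12 of the data's total sum of
squares) the most parsimonious fit — the one with the largest amplitude
disparity, i.e. closest to a single exponential — is preferred, remaining
ties resolved by grid order.

**Dose–response.** $E(c) = E_{max}c^h/(EC_{50}^h + c^h)$ with $h = 1$ fixed
by default (only EC50 and maximal effect are reported in the convention
this follows). An all-zero effect returns $E_{max} = 0$ with EC50 flagged
unidentifiable rather than a spurious fit.

**Trace simulator.** Per test potential, the current rises biexponentially
toward $g_{max}\,p_\infty(V)\,(V - E_{rev})$ and decays biexponentially on
the tail step, with voltage-independent kinetics; additive Gaussian noise is
optional and seeded. Voltage-independent taus are a deliberate
simplification: they make reference-normalised tail peaks reproduce the
Boltzmann open probabilities exactly, which is what gives the noiseless
round trip (simulate → `gv_from_tails` → `boltzmann_fit` →
`biexp_fit`) its 1e-4-relative recovery guarantee. Real channels have
voltage-dependent kinetics and inactivation hooks; neither is modelled, and
no leak subtraction or series-resistance correction is applied.

## Orchestration

`run_compare()` executes read → superpose → (window) → RMSD/RMSF/DCCM per
replicate → condition means → delta → block summaries → contact table, for
exactly two conditions (the with/without design); any stage error aborts
with the stage name and replicate id. Reports carry a provenance block
(seed, replicate counts, window, package version) and serialise to labelled
delimited text plus JSON. `run_simulate()` and `run_ephys()` drive the
generators and the fit batch; per-file ephys failures are collected without
aborting, and the report's exit status reflects them. The R functions are
the primary interface; `inst/cli/kvcoupling.R` is a thin `optparse` wrapper
exposing them as `simulate` / `compare` / `ephys-fit` subcommands with exit
codes 0/1/2 (ok / user error / stage failure).

## Problem sizes and numerical tolerances

The validation suite uses sizes chosen to make sampling error negligible
relative to each tolerance while keeping runs interactive: DCCM oracle
equivalence on ≤5 residues × ≤20 frames at 1e-12 (pure arithmetic);
correlation recovery at 2,000 frames within ±0.05 (sampling error
$\approx n^{-1/2}$); the RMSF closed form at 10,000 frames within 2%;
rigid-overlay invariance at 1e-6; the null-design delta-DCCM bound of 0.1 at
2,000 frames per replicate; Boltzmann Monte-Carlo recovery over 50 seeds
with 1% additive noise (median $|\hat V_{1/2} - V_{1/2}| < 1$ mV). Matrix
entries are clamped to [−1, 1] only against floating-point overshoot
(≤ 1e-15), never to mask estimator faults.

## Known limitations

* No binary trajectory formats (DCD/XTC) — multi-model PDB and the plain
  text formats only — and no topology or force-field parsing.
* DCCM values depend on the superposition protocol; comparisons across
  packages require matching fit selections.
* Contact persistence depends on cutoff conventions; no angle terms in the
  aromatic criterion.
* The ephys model has no Markov gating states, inactivation, leak or
  series-resistance artefacts; tail "hooks" from recovery of inactivated
  channels are not modelled, and no inward-tail correction is applied by
  default.
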