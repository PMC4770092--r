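---
title: "Models and methods behind lidforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lidforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidforce)
```

`lidforce` analyses passive-mode dual-trap optical tweezers experiments
on enzyme lid closing. This vignette is the package's own account of the
models it implements, the assumptions behind them, the parameters that
matter, and the numerical and design choices that were genuinely open.

## The physical picture

A single adenylate kinase molecule is held between two optically trapped
beads through dsDNA handles attached at residues flanking the mobile
lids. At fixed trap separation the tether tension is quasi-constant and
the enzyme hops between an extended lid-open and a contracted lid-closed
conformation, changing the construct length by about 1.6 nm when a
bisubstrate inhibitor drives full closing of both lids. Everything the
package computes rests on four model layers:

1. **Tether mechanics.** The handles follow the Marko–Siggia worm-like
   chain (WLC) interpolation; an optional enthalpic stretch modulus
   extends it to extensible chains. The dumbbell is a series system of
   two harmonic traps (effective stiffness $k_\mathrm{eff} = (1/k_1 +
   1/k_2)^{-1}$), the handles, and the protein. At separation $D$ and
   protein extension $x_p$ the tension solves $F = k_\mathrm{eff}(D -
   x_p - x_\mathrm{DNA}(F))$, a monotone scalar equation solved by
   bracketed root finding.

2. **Two-state kinetics under load.** Opening and closing are a
   continuous-time telegraph with Bell rates $k_i(F) = k_{0,i}
   \exp(F\Delta x_i/k_BT)$. The sign convention is that positive
   $\Delta x$ accelerates a rate with force; closing typically carries a
   small negative $\Delta x$ (it moves against the load), opening a
   large positive one. Closing is bimolecular in the ligand: its
   propensity is proportional to concentration, while opening is
   concentration independent. The force-(in)dependence of closing is the
   kinetic discriminator between induced-fit binding (force-independent
   closing) and conformational selection (closing carries the full
   conformational change): force suppresses a pre-existing closed state,
   so under conformational selection the apparent closing rate would
   fall steeply with load.

3. **Binding thermodynamics.** Ligand occupancy of the open state blocks
   inhibitor rebinding, lengthening open dwells by the factor
   $1 + [L]/K_D$; hence $\Delta\Delta G([L]) = k_BT\ln(1 + [L]/K_D)$ in
   the competition assay, and the equilibrium unfolding free energy of
   the ATP lid grows as $\Delta G([L]) = \Delta G^0 + k_BT \ln(1 +
   [L]/K_D)$. The two routes to $K_D$ are independent and are
   cross-checked against each other in the tests.

4. **Partial closing.** Substrates shift the open level by $\Delta x\,
   p_\mathrm{closed}(F)$ where $p_\mathrm{closed}(F) = 1/(1 +
   (k_{0,\mathrm{open}}/k_{0,\mathrm{close}})e^{F\Delta x/k_BT})$, so
   the fraction of full closing is $f(F) = (\Delta x / L_\mathrm{full}
   (F))\,p_\mathrm{closed}(F)$. The concentration dependence follows a
   four-state scheme (open/closed × bound/unbound) whose unbound
   conformational equilibrium is fixed at the published unbound rates
   (opening:closing 6500:2000 s⁻¹) rather than fitted; with the
   unbound-closed population negligible under load, the closed-state
   probability reduces to
   $$P_\mathrm{closed}([L]) = \frac{K_\mathrm{conf}[L]/K_\mathrm{close}}
   {1 + [L]/K_\mathrm{open} + K_\mathrm{conf}[L]/K_\mathrm{close}},
   \qquad K_\mathrm{conf} = \frac{2000}{6500}.$$

## Parameters, units, defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| temperature | K | 298 | room temperature; $k_BT$ = 4.114 pN nm |
| DNA persistence length | nm | 50 | field-standard dsDNA value |
| DNA contour length | nm | 360 | handle length of the assay |
| polypeptide persistence | nm | 0.7 | standard unfolded-chain value |
| polypeptide contour | nm/residue | 0.365 | standard crystallographic value |
| trap stiffness $k_1, k_2$ | pN/nm | 0.3 | typical high-resolution dual trap |
| protein contraction | nm | 1.6 | full two-lid closing distance |
| sampling / storage rate | Hz | 150000 / 30000 | acquisition averaged 5:1 to storage |
| OU noise SD | nm | 0.35 | see below |
| OU corner frequency | Hz | 5000 | lumped bead + tether relaxation |
| display filter cutoff | Hz | 37.5 | display convention; never used before detection |
| transition window (FEC fits) | pN | 13–20 | the equilibrium hump lives here |
| folded-fit crossover | pN | 10 | limits low-force noise in the area rule |
| unbound opening:closing | s⁻¹ | 6500:2000 | published unbound lid equilibrium |

All defaults are configurable; none is hard-coded at a call site.

## What the generator emulates, and what it does not

The synthetic generator produces exactly the statistical structure the
analysis assumes: Gillespie dwells with Bell rates evaluated at each
state's self-consistent tether force (rates constant within a dwell),
deflection levels from the trap–WLC force balance, additive discrete
Ornstein–Uhlenbeck noise at the acquisition rate, and 5:1 block
averaging to the storage rate — averaging, not decimation, to mirror how
the instrument stores data. Force–distance curves are generated in the
fast-exchange (equilibrium) limit, in which the measured force is the
Boltzmann-weighted mixture of the folded and unfolded branch forces; a
stochastic hopping mode exists behind a flag for detector stress tests.

The noise model deserves a note. Neither the signal-to-noise ratio nor
the bead relaxation spectrum of the original instrument is published, so
both are package choices: a single OU process (corner 5 kHz) lumps bead
and tether relaxation, and the stationary SD default of 0.35 nm was
chosen once so that 5 ms dwells are cleanly resolvable in the stored
30 kHz signal — the regime the assay operates in. At substantially
higher noise or strong noise correlation the Gaussian-emission HMM
over-segments dwells, and the dead-time diagnostic reported with every
dwell set (two sample periods) is the first place that bias becomes
visible.

Deliberately *not* emulated: instrument drift, hydrodynamic coupling
between the beads, multiple tethers, intra-dwell force fluctuations
feeding back into the rates, and missed-event (dead-time) corrections —
the analysis applies none, so the generator does not either. Passing
tests therefore demonstrate correctness of the analysis under its own
model assumptions, not robustness to instrument pathologies absent from
that model.

## Numerical choices

- **WLC inversion** is by bracketed bisection driven to near machine
  precision in extension (2×10⁻¹³ relative), because the force diverges
  at the contour length and a loose extension tolerance would spoil the
  1e-9 relative force roundtrip the package guarantees.
- **Slack geometries**: an inextensible WLC keeps an arbitrarily small
  entropic tension at any extension, so "no tension" is a threshold —
  tensions below 0.05 pN are reported as slack with zero force.
- **HMM**: Gaussian emissions (block-averaged OU noise is near
  Gaussian); scaled forward–backward in compiled code; convergence at
  Δlog-likelihood < 1e-8 per sample or 500 iterations; initialization
  from a 2-means split; Viterbi ties break toward staying in the
  previous state (hysteresis). Detection runs on the stored 30 kHz
  stream — "unfiltered" means no display filtering, which the fitter
  enforces by rejecting traces whose history records a low-pass.
  Degenerate fits (levels within 0.1 noise SD, level separation below
  half a noise SD, or a nearly memoryless fitted chain) raise
  diagnostics instead of returning garbage.
- **Censoring**: the first and last dwells of every trace are truncated
  by the observation window and excluded from rate estimation, the
  standard treatment for exponential maximum likelihood.
- **Bell fits** run on log rates with $(k/\sigma_k)^2$ weights
  (variance stabilizing; the error model of the source data is not
  published, so weighting is configurable). On the log scale the global
  model is linear in its parameters, so weighted linear least squares
  delivers the exact optimum that an iterative Levenberg–Marquardt
  search would reach, with the same 1 s.d. statistical errors.
- **Nonlinear fits** ($K_D$, closing-fraction, branch elasticity, the
  concentration model) use Levenberg–Marquardt (`minpack.lm`), with
  positive-definite parameters fitted on the log scale and delta-method
  errors propagated back.
- **Area rule**: trapezoidal integration over trap distance; the
  composite total (folded fit below the 10 pN crossover, measured curve
  above) minus the unfolded-branch area; linker and trap work cancel in
  the subtraction. The integral is grid-stable (2× resampling shifts
  ΔG by < 0.1 kBT in the tests).
- **Projection**: the 1D coordinate is the sum of the two lid-coordinate
  displacements from the global minimum — the simplest coordinate
  "roughly resembling" the lid-to-lid distance under the assumption
  that the two lid motions are mainly orthogonal. The combination rule
  is a swappable argument, and both within-bin reductions (Boltzmann
  marginalization, default; minimum) are kept and recorded in
  provenance. Minimum ties break toward the smallest coordinates,
  deterministically, and are flagged. The pN·Å → $k_BT$ conversion goes
  through the constants object, never a literal.

## Open design decisions, resolved

- **Equilibrium free energies** are computed as $-k_BT\ln(k_\mathrm{
  close}/k_\mathrm{open})$ at the force the rates refer to, and at zero
  force from the zero-force extrapolated rates, with no additional
  elastic-work terms beyond the constant-force transform. The exact
  historical recipe this mirrors is under-specified in the source
  literature; this simplified convention is the package's documented
  choice.
- **$L_\mathrm{full}(F)$**, the inhibitor-only closing distance entering
  the fraction normalization, is interpolated linearly between measured
  forces (constant if a scalar is given).
- **One $\Delta x$, two roles**: in the fraction model the same
  $\Delta x$ appears in the Boltzmann exponent and in the normalization
  amplitude; the package treats them as one parameter, which is the
  reading consistent with a single substrate-induced conformational
  change of that size.
- **Signal convention**: the trace signal is the construct extension
  (trap separation minus total bead deflection), so the constant-force
  transform is literally "subtract the per-point DNA handle extension"
  and the corrected signal is the protein extension.
- **CLI**: the package's users drive it from R; `run_pipeline()` plus
  the per-stage functions are the orchestration surface, emitting a
  deterministic JSON report with config hash, seed and version.

## Problem sizes

The test suite and the demonstration pipeline are sized to run
comfortably on one CPU: dwell-grid recoveries use 4 forces × 3
concentrations × 500 dwells; HMM recovery traces carry 200–600
transitions at 30 kHz for a few seconds; force–distance curves hold
~400 points across 330–510 nm; landscape grids are ~40×40. These sizes
were chosen so that 2-s.d. recovery criteria are meaningful (statistical
errors a few percent), and scale linearly if larger studies are needed.

## Known limitations

- Exactly two states; no missed-event correction (the dead-time
  diagnostic makes the residual bias visible instead).
- Gaussian emissions and white-noise likelihood: strongly correlated
  noise at the storage rate biases dwell segmentation.
- The fast nucleotide-exchange fluctuations themselves are not modelled
  (they are unresolved in the data this analysis addresses); only their
  average effect on the open level enters.
- The 2D free-energy landscapes are inputs, not outputs: the package
  projects and tilts them but does not run any sampling.
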