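---
title: "The quorum-sensing model of Th1/Th2 effector choice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quorum-sensing model of Th1/Th2 effector choice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`thquorum` simulates collective effector choice in a group of CD4+ helper
T cells deciding between the Th1 and Th2 programs.  Four state variables
describe the group: the master transcription factors T-bet (`TF1`) and GATA3
(`TF2`), measured in molecules per cell and confined within cells, and the
master cytokines IFN-γ (`CY1`) and IL-4 (`CY2`), measured as concentrations
in the shared extracellular space.  Each transcription factor self-activates
and cross-inhibits its rival; each is additionally induced by its own-axis
cytokine, gated by cross-inhibition from the rival cytokine; and each
cytokine is secreted under control of its own-axis factor, repressed by the
rival factor and the rival cytokine, and removed by first-order kinetics.
All interactions are Hill functions:

$$
\frac{dTF_1}{dt} =
\Bigl(b + p_1\frac{TF_1^{h_p}}{P_1^{h_p}+TF_1^{h_p}}\Bigr)
\frac{X_2^{h_x}}{X_2^{h_x}+TF_2^{h_x}}
+ s_1\frac{CY_1^{h_s}}{S_1^{h_s}+CY_1^{h_s}}
\frac{Z_2^{h_z}}{Z_2^{h_z}+CY_2^{h_z}} - d_{TF1}\,TF_1
$$

$$
\frac{dCY_1}{dt} =
\sigma\, a_1\frac{TF_1^{h_a}}{A_1^{h_a}+TF_1^{h_a}}
\frac{R_2^{h_r}}{R_2^{h_r}+TF_2^{h_r}}
\frac{U_2^{h_u}}{U_2^{h_u}+CY_2^{h_u}} - d_{CY1}\,CY_1
$$

with the `TF2`/`CY2` equations the mirror images (indices swapped), and
$\sigma \in [0,1]$ the *secretion scale* — the model's handle on
antibody-mediated cytokine blocking, applied only to the maximal secretion
rates.

Three extensions turn this toggle into a collective decision model:

1. **Cell density.**  Transcription factors are per-cell counts and do not
   see density, but cytokine *concentrations* do.  Secretion compacts into
   less extracellular volume as density ρ rises, and removal has a
   cell-driven consumption part plus free decay:
   $a_i(\rho) = a_{i,\mathrm{base}}\,\rho/\rho_\mathrm{ref}$ and
   $d_{CY_i}(\rho) = d_\mathrm{consume}\,\rho/\rho_\mathrm{ref} +
   d_\mathrm{free}$.  Because $d_\mathrm{free} > 0$, production outpaces
   removal as density grows: the production:removal ratio is strictly
   increasing in ρ, and cytokines turn over faster *and* accumulate higher
   in vivo (~10⁹ cells/mL) than in culture (~10⁶ cells/mL).

2. **APC instruction.**  Antigen-presenting cells secrete effector-driving
   cytokines directly onto T cells, so instruction enters as additive
   constants `APC1`, `APC2` augmenting every appearance of `CY1`, `CY2`
   except the decay terms.  `apc_constants()` maps APC counts to constants
   linearly with a per-APC strength `kappa_apc`.

3. **Stochasticity.**  Each equation gains an independent multiplicative
   Brownian term $n_X\,X\,dW_X$, producing lognormal-type fluctuations with
   the large positive skew characteristic of single-cell expression data.
   Many sample paths of the SDE system stand in for the distribution of
   expression across a cell population.

## The default parameter set is a calibrated stand-in

The package does not ship literature-fitted rate constants.  The defaults in
`model_parameters()` form a **symmetric, calibrated stand-in** chosen once to
reproduce the regime structure that defines the biology, and then frozen:

* at 2×10⁶ cells/mL with full secretion, the **mixed** state
  (TF1 = TF2 ≈ 92, θ = 0.5) is the *unique* stable equilibrium;
* with secretion blocked (σ = 0), the transcription-factor toggle is
  **bistable**: two polarized states, the mixed state a saddle;
* at 10⁹ cells/mL the mixed state is unstable and exactly two polarized
  states are stable — the quorum regime.

Mechanically, the calibration works through two oppositely-directed
cytokine effects.  At culture density the cytokine boost to both factors
lifts the mixed state far above the cross-inhibition threshold `X`, where
the toggle's asymmetric feedback is weak — cytokines *stabilize* mixing.
The polarized states do not survive there because even the suppressed
factor's basal leak secretes enough cytokine (secretion half-saturation
`A = 5` molecules/cell is low) to re-induce its own axis and pull the cell
back to the mixed state.  At in-vivo density the accumulated dominant
cytokine (≈ 222 concentration units at a pole) shuts that rescue down
through the cytokine–cytokine inhibition gate `U` and the induction gate
`Z`, and the fast, strong cytokine response to any factor asymmetry turns
into a cross-scale positive feedback that destabilizes the mixed state.
The quorum density for the default set is ≈ 4.8×10⁶ cells/mL — strictly
between the culture and lymph-node densities, on the in-vivo side of
anything achievable in a dish.

Time is in hours.  TF decay 0.1 h⁻¹ (~7 h half-life, a realistic protein
turnover); free cytokine decay 1 h⁻¹ (fast, as for many cytokine-regulating
molecules); consumption 0.008 h⁻¹ at the reference density 10⁶ cells/mL, so
removal at 10⁹ cells/mL is 9 h⁻¹ and the production:removal ratio saturates
near `a_base/d_consume` = 250.

Two further constants were calibrated against the canonical instruction
scenario and then frozen:

* **`kappa_apc` = 0.0108.**  Ten APCs at a 6:4 Th1 bias must commit the
  quorum at 10⁹ cells/mL (they do for any tested strength), and a later
  switch to 1000 all-Th2 APCs must be able to reverse the commitment *only
  early*.  The flooded system loses its committed attractor through a
  saddle-node when the flood constant `1000·kappa_apc` reaches ≈ `Z`;
  just below that point the reversal window is maximal.  The default gives
  a window of ≈ 12.9 h.  This is shorter than the ~20 h the original
  analysis reports; with the stand-in rates, commitment is fast enough that
  no admissible instruction strength stretches the window further, and we
  report the model's own value rather than forcing the printed one.

* **Default volatility `n` = 0.1** (10% per √h on all four variables),
  chosen so that one-week in-vitro ensembles reproduce the qualitative
  distribution shapes: substantial central mass with secretion on, a clean
  U-shape with secretion blocked.  Larger volatilities broaden the
  secretion-on distribution toward uniformity but wash out the blocked
  U-shape; the volatility scans explore that axis explicitly.

## Deterministic analyses

`integrate_ode()` integrates with `deSolve::lsoda` (stiff-capable) at
relative tolerance 1e-8, segment by segment across instruction switches so
breakpoints are exact.  `find_equilibria()` runs a damped Newton iteration
(compiled, central-difference Jacobian, projection onto the non-negative
orthant) from a log-spaced grid of transcription-factor starts spanning
10⁻² to 10² times the Hill thresholds, with cytokines seeded at their
quasi-steady levels; roots are accepted below a normalized residual of
10⁻⁸, deduplicated at 10⁻⁶ relative tolerance, and classified by the
eigenvalues of the numerically evaluated Jacobian.  The finder is checked
in the test suite against endpoint clustering of brute-force integration
from a 5⁴ grid of initial conditions.

The bisections — critical secretion scale, quorum density (log-scale), and
reversal window — all return points whose two-sided neighbourhoods carry
opposite classifications, and track the mixed branch by Newton continuation
from the previous solution.

`scale_decomposition()` formalizes the within-scale versus cross-scale
stability argument.  At a symmetric mixed equilibrium the destabilizing
direction is the polarization mode (TF1 ↑, TF2 ↓, CY1 ↑, CY2 ↓).
Compressing the Jacobian onto that mode's TF and CY components yields a
2×2 matrix whose diagonal holds the two *within-scale* feedbacks (factor
self-activation and cross-inhibition plus decay; cytokine cross-inhibition
plus removal) and whose off-diagonal holds the two *cross-scale* couplings
(cytokines inducing factors; factors driving secretion).  With both
within-scale feedbacks stabilizing, the mixed state is stable exactly while
their product exceeds the cross-scale product; the quorum transition is the
point where the cross-scale total overtakes the within-scale net effect.
For asymmetric parameter sets the projection uses the least-stable
eigenmode instead of the exact polarization mode, which keeps the verdict
aligned with the full-Jacobian eigenvalue (verified over perturbation
samples in the tests).

A deliberate degeneracy: from an exactly symmetric state in a polarized
regime with unbiased instruction, the ODE stays on the (unstable) symmetric
manifold and the trajectory is reported as mixed/undecided rather than
perturbed — the deterministic path is what it is.  Note that at 10⁹
cells/mL the manifold is so unstable (leading eigenvalue ≈ 7 h⁻¹) that
solver round-off alone will eventually polarize a nominally symmetric run;
symmetric-manifold assertions in the tests are therefore made in the stable
mixed regime.

## Stochastic simulation

`simulate_sde()` uses Euler–Maruyama in natural coordinates with step
`dt = 0.01` h — small against the fastest relaxation in the system
(cytokine removal at 9 h⁻¹ in vivo) — clamping each component at zero after
each step, consistent with multiplicative noise vanishing at the origin.
Log-space integration was rejected because the drift has additive terms
that act at zero.  All normal increments are drawn from R's RNG *outside*
the compiled stepper, so reproducibility is governed entirely by the seed;
per-path seeds derive from an ensemble master seed.  The zero-noise path
reproduces the ODE solution (relative sup-error ≈ 0.6% at the default
step, halving with the step), and identical seeds give bitwise-identical
paths.

`balance_distribution()` reduces an ensemble to the balance index
θ = TF1/(TF1+TF2) (θ = 0.5 for the all-zero state) and labels the
histogram shape by a fixed rule on 10 equal bins: *U-shaped* when both
outer bins exceed twice the mean inner-bin mass and the two middle bins
hold at most half of it; *uniform* when the max/min bin ratio is under 3;
*unimodal-central* when the fullest bin is central.  Attractor labels use
θ > 0.8 for Th1 and θ < 0.2 for Th2; anything between is mixed.  The
original analyses describe these shapes and commitments only qualitatively;
the explicit cutoffs make them testable and are used consistently
everywhere.

## Discernment experiments

Time-varying instruction is a piecewise-constant schedule; the generator
draws 1–6 segments with log-uniform durations on [10, 250] h over a 500 h
horizon and per-segment Th1-bias from {0, 0.25, 0.4, 0.6, 0.75, 1} at fixed
total strength.  The *optimal response* starts on the side of the initial
majority and switches only when the schedule holds a complete (100%)
opposite bias continuously for at least the sensitivity duration τ
(defaults 24, 48, 96 h), taking effect the moment the criterion is met.
*Tracking performance* is the time-fraction of agreement between a path's
attractor label and the target (mixed counts as disagreement — a quorum
ought to be committed), pooled over paths, scored from 48 h onward so the
initial sparking transient is not charged against either side; *relative*
performance divides each volatility cell by the best cell.

The schedules' total strength is the late-infection level of the reversal
scenario (1000 APCs, i.e. `1000*kappa_apc` ≈ `Z`), not the 10-APC sparking
level.  This is a considered choice: at the sparking level, instruction is
three orders of magnitude weaker than a committed quorum's own cytokine
signal, stochastic attractor switching is instruction-blind, and *no*
volatility level permits tracking — performance just decays with noise.
Near the flood saddle-node, instruction tilts the escape landscape without
deterministically forcing it, and the signature behaviour appears:
tracking performance peaks at an interior volatility (~10%) for every
sensitivity τ, collapses at high volatility (paths switch at random), and
in the 2-D scan the best cell has cytokine volatility *above*
transcription-factor volatility — cytokine noise perturbs the quorum's
shared memory and drives re-decisions, while quiet factors keep each
decision crisply classifiable.

The 2-D cell differences (~0.005 in mean performance) are an order smaller
than the 1-D ones, so the 2-D scan averages over 60 schedules × 20 paths
where the 1-D scans use 20 × 20; grids, horizons, step and density are
identical.

## Sensitivity analyses

`sample_parameters()` multiplies every rate and threshold by independent
uniform draws from [1−amp, 1+amp]; Hill exponents are held fixed by default
(scaling an exponent by ±90% changes the model class, not its rates).
`regime_scan()` counts stable equilibria per perturbed set and compares
with the base regime; `effect_sizes()` fits main-effects linear models of
the tracked equilibrium's balance index and total factor level on the
multipliers ("near" = amp 0.1), reporting each parameter's predicted
response change across its sampled range as a percent of the base response.

Under the stand-in set the low-density regime is fragile (mismatches from
10% variation, with well over half of sets keeping the original regime
throughout the sweep) and the high-density regime is robust through 40%
variation, with a few percent of sets finding new regimes at 50%.  The
per-parameter net effects on the mixed equilibrium's balance at low density
reach ~40% of base for the factor decay rates: the stand-in's polarization
mode is deliberately soft at culture density (that softness *is* the
nearness to the quorum bifurcation), so the balance responds strongly to
decay asymmetry.  A parameter set with the original study's stiffer mixed
equilibrium would show smaller effects; without its printed values the
package reports its own.

## What the synthetic conditions do and do not emulate

The generator-and-ensemble machinery emulates: density-dependent cytokine
kinetics, conflicting and time-varying instruction, and cell-to-cell
expression variability with lognormal character.  It does **not** emulate
T-cell proliferation or death, migration in and out of the lymph node,
spatial cytokine gradients, receptor-level kinetics, the 72-h
APC-refractory period, epigenetic entrenchment of commitment, or additional
effector lineages.  Passing tests therefore demonstrate the collective
decision logic of the four-variable model under these idealized conditions,
not a quantitative fit to any particular culture or infection.

## Problem sizes

The test suite and the acceptance script run at desk scale: 100-path
ensembles for distribution shapes, 20 schedules × 20 paths per volatility
cell (60 × 20 for the 2-D scan), 100-draw decomposition-consistency
samples, 200–500 parameter sets per sensitivity amplitude, and a 5⁴
brute-force oracle grid.  Full-breadth variants (1000 paths, 200 schedules
× 100 paths) are available through `run_experiment(..., scale = "paper")`
and the function arguments; breadth is the only difference.
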