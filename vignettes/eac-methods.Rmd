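---
title: "Equivalent atomic charges from the field response of QM/MM interaction energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent atomic charges from the field response of QM/MM interaction energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eacfield)
```

## The physical picture

Photodissociated CO in myoglobin's distal-pocket docking site adopts two
antiparallel orientations, B1 and B2, distinguished by the Fe···C≡O angle
(obtuse ≈ 115° vs acute ≈ 50–55°). The two states are stabilized
electrostatically: the protein environment exerts an electric field along
the CO bond, and the sign of that field relative to the molecular axis is
what differs between the orientations. How accurately a QM/MM scheme
captures the interaction between the CO (QM) and its surroundings (MM
point charges) therefore shows up directly in the simulated B1/B2
population ratio, and methods with and without electron correlation
(HF, B3LYP, MP2) disagree substantially.

`eacfield` implements the statistical analysis layer of that problem. It
does **not** run molecular dynamics or any electronic-structure
calculation; it consumes per-frame geometries, point charges and energy
pairs (E_total in the embedding, E_self in vacuum) and asks: how does the
interaction energy E_EI = E_total − E_self respond to the field along the
bond, and what minimal physical model reproduces that response?

## Field and energies from point charges

The potential at a probe atom center is the bare Coulomb sum
φ(r) = (1/ε_eff) Σ_j q_j/|r − r_j| over all environment atoms, and the mean
field along the bond is F = (φ(r_C) − φ(r_O))/|r_CO|, positive from C
toward O. Unit choices:

* positions in Å, charges in e; potentials (e/Å) and fields (e/Å²) are kept
  in these native units;
* the single conversion constant `K_COUL` = 332.0636 kcal mol⁻¹ Å e⁻² is
  applied exactly once, when an energy is formed. Every intermediate
  quantity is therefore auditable by hand.
* `eps_eff` is a dimensionless divisor, default 1.0 — appropriate when the
  solvent is explicit and its charges are part of the sum.

Two guards keep malformed inputs from producing silently absurd numbers: an
environment atom closer than 0.5 Å to an evaluation point is an error (such
overlaps cannot occur in a sane trajectory), and a CO bond length outside
[0.8, 1.6] Å warns. No distance cutoff is applied by default, since the sum
is defined over all residues; an optional `cutoff` argument reproduces the
finite electrostatic cutoff of typical QM/MM engines (25 Å) when needed.

The classical (point-charge) interaction energy of the probe uses a linear
polarizable charge for the O atom, q_O = αF + q0 with q_C = −q_O. In a
uniform field this gives E = −K_COUL·(αF + q0)·F·l: an even, purely
quadratic function of F when q0 = 0, with its extremum at F = −q0/(2α). The
sign convention (stabilizing, E < 0 for α > 0) is the one that falls out of
the point-charge energy with the linear charge model; the bare interaction
form is used, without the ½ self-polarization work factor — the choice is a
convention and affects only the absolute scale, which nothing downstream
consumes. Because a symmetric quadratic responds identically to fields of
either sign, this classical term cannot distinguish B1 from B2; the
asymmetry lives in the full QM/MM energies.

## The segmented fit and the EAC model

The central estimator, `eac_fit()`, partitions (F, E_EI) samples by the
sign of F and fits an ordinary least-squares line with a **free intercept**
on each side. The constant-dipole model implies zero intercepts, but
forcing the fit through the origin would make the slopes sensitive to any
small offset in the energies; with free intercepts the estimator reduces to
the ideal model when the intercepts come out ≈ 0 (they do, and they are
reported). Samples with F exactly 0 are a measure-zero set in floating
point; they are excluded from both segments and counted, which is the only
deterministic rule that needs no arbitrary side assignment.

Each slope k maps to an equivalent atomic charge via q = −k/(K_COUL·l).
The minus sign encodes the convention that a stabilizing positive-field
branch (k1 < 0) corresponds to a positive O charge — the C⁻O⁺ state — and
the negative-field branch to C⁺O⁻. The dipole arm defaults to the fixed
l = 1.14 Å that the CO bond fluctuates around; per-frame bond lengths can
be used during correction instead, but the fixed arm is the default
treatment. All externally comparable quantities are unsigned ratios
(|k1|/|k2| = |q_pos|/|q_neg|), so the internal sign convention never leaks.

A nonparametric bootstrap (frame resampling, default 1000 draws, seeded)
attaches a percentile confidence interval to k1/k2. The point estimate
needs none, but a reusable pipeline should not report a ratio of two noisy
slopes without an uncertainty.

The correction scheme replaces a low-level method's linear field response
with the high-level one: E_corr = E_low − E_EAC(low, F) + E_EAC(high, F).
On data generated exactly by the low-level model this reproduces the
high-level energies identically — the algebraic cancellation is one of the
package's acceptance-tested invariants. Agreement is always scored as both
squared Pearson correlation *and* mean unsigned error, because r² alone is
blind to sign flips and affine offsets.

## B-state classification

`fe_co_angle()` is the arccos of normalized dot products at the C atom;
`classify_state()` uses the 90° boundary with ties assigned to B2. The
population modes sit at ~115° and ~50–55°, far from the boundary, so the
tie-break cannot move populations; it exists purely so the classification
is a deterministic, testable function. Angles are counted per saved frame
with no smoothing or reweighting. The acute-state mode is quoted in the
literature as ~50° or ~55° depending on the analysis; the generator default
splits the difference at 52.5°.

## What the synthetic generator emulates — and what it does not

`generator_truth()` fixes the study conditions:

* **EAC models**: the published HF (0.1638/−0.1979 e), B3LYP
  (0.2196/−0.1222 e) and MP2 (0.2541/−0.0843 e) charge pairs at l = 1.14 Å.
* **Fields**: sign drawn with probability 0.5, magnitude half-normal with
  scale 0.02 e/Å². The scale is chosen so that, with the charges above,
  interaction energies span a few kcal/mol — the scale on which the
  correction residuals (MUE ≈ 0.1 kcal/mol) are meaningful. The symmetric
  default balances the two segments; an asymmetry knob (`p_pos`) exists
  because real trajectories are not guaranteed balanced.
* **Noise**: Gaussian, σ = 0.1 kcal/mol on energies and 0.005 e on ESP
  charges — calibrated so the corrected-versus-target error lands on the
  0.1 kcal/mol scale of real QM/MM data. This is a calibration choice, not
  a fit to anything.
* **ESP charge response**: α = 2.0 e per (e/Å²) with a near-zero gas-phase
  charge q0 = 0.005 e. Only the linearity and the sign pattern matter
  downstream; the absolute α is unconstrained by any published number.
* **Bond lengths**: N(1.14, 0.02) Å, with a weak linear energy coupling of
  0.3 kcal/mol/Å — small enough that the k1/k2 statistic is insensitive to
  it, which the tests verify.
* **Angles**: a two-component circular mixture (normal draws wrapped to
  [0, 360) and folded into [0, 180]) at 115° and 52.5° with 10° spread and
  weights 3.45:1 by default. The wrapped/folded-normal choice is ours; only
  the mode locations and weights are externally meaningful.
* **Energy bookkeeping**: the generator emits E_total = E_self + E_EI with
  per-method E_self constants, so the decomposition stage is genuinely
  exercised; gauge invariance makes the constants arbitrary.

Microscopic scenes (`generate_scene()`) place force-field-like charges
(±0.4 e) uniformly in a 3–25 Å shell with the net charge balanced to zero,
and the per-frame field is always computed by `field_along_bond()` on those
charges, never shortcut from the generator parameters.

What the generator does **not** emulate: real CO dynamics, hydrogen-bonding
to His64, water structure, multipole and charge-penetration effects, or any
correlation between the field a frame experiences and its B state. Passing
tests therefore demonstrate that the estimators recover known statistical
structure — linearity, slopes, mixtures — not that the physical claims hold
for real trajectories. The published real-data agreement figures
(r² = 0.9921/0.9995, MUE = 0.101/0.026 kcal/mol for corrected HF/B3LYP
against MP2) require the original quantum-chemistry energies and are not
reproducible here; the package substitutes the noiseless-limit exactness
identity plus a monotone-degradation-in-noise suite.

## Numerical choices and degenerate inputs

* Detrending on bond length (optional, default off) is plain OLS removal of
  the centered linear component, mean-preserving and idempotent; how the
  bond-length influence should be removed is not uniquely determined, and
  OLS is the simplest reproducible reading. It is implemented as a
  pre-pass before the field regression, and the fitted slope is logged.
* Segment fits require ≥ 2 samples per side; a zero-variance regressor, a
  zero negative-side slope and zero-variance agreement inputs are all
  explicit errors naming the offending quantity.
* r² is squared Pearson correlation (not regression r² against the
  identity line); MUE is the stricter companion and is always reported.
* Emitted tables carry 10 significant digits so byte-level determinism of
  reruns is testable; all randomness flows through a single integer seed.
* An all-B1 angle series yields an infinite ratio with a warning rather
  than an error, so population scans do not abort on extreme inputs.

## Problem sizes

The test-suite and acceptance runs use 10⁴ frames for stochastic recovery
checks (matching the 10⁴ saved configurations a 2 ns trajectory sampled
every 200 fs provides), a few hundred frames for exact noiseless
identities, and 100 randomized scenes of up to 200 atoms for the
Coulomb-sum oracle comparison — sizes at which every check runs in seconds
while leaving estimator standard errors far inside the asserted
tolerances.

## Known limitations

* The absolute field scale is internal: published figures do not fix the
  unit of their field axes, so only slope *ratios* (and charge ratios) are
  externally comparable, never absolute slopes.
* The EAC model is piecewise linear with a hinge at F = 0 by construction;
  it cannot represent curvature in the energy–field relation (the classical
  quadratic term is handled separately).
* The printed MP2 charge pair implies |k1|/|k2| = 3.014 while the published
  table prints 3.02 — a rounding-level inconsistency in the source values;
  comparisons use a ±0.01 tolerance that covers it.
* `read_pqr()` accepts the common whitespace-delimited PQR dialects (with
  or without a chain column) but not exotic variants with insertion codes
  spliced into the residue field.
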