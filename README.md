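# eacfield

Photodissociated CO in the distal heme pocket of myoglobin sits in two
antiparallel orientations — B1 (obtuse Fe···C≡O angle, mode near 115°) and B2
(acute angle, mode near 50–55°) — whose population ratio is exquisitely
sensitive to how a QM/MM simulation describes the electrostatic interaction
between the CO probe and its surroundings. `eacfield` implements the analysis
that connects those populations to electrostatics: it computes the electric
field along the probe bond from the environment's point charges, extracts
QM/MM electrostatic interaction energies from total and gas-phase energies,
fits the sign-segmented linear energy–field relation, derives
**electric-field-based equivalent atomic charges (EAC)**, and uses them to
correct cheap-method interaction energies toward a correlated target. It is
written for computational chemists and structural-bioinformatics researchers
who post-process QM/MM trajectories (or want a fully synthetic testbed for
such analyses).

## The model

For every saved frame, the electrostatic potential at the probe atom centers
is the bare Coulomb sum over environment atoms *j* with charge *q_j*,

φ(r) = (1/ε_eff) Σ_j q_j / |r − r_j|    (e/Å),

and the mean field along the C→O bond is

F = (φ(r_C) − φ(r_O)) / |r_CO|    (e/Å², positive from C toward O).

Interaction energies E_EI = E_total − E_self, plotted against F, are linear
on each sign of the field with different slopes k1 (F > 0) and k2 (F < 0).
That is the signature of a constant-moment dipole, E = **μ**·**F** with
**μ** = q **l**: ordinary least squares on each segment gives k1 and k2, and

q = −k / (K_COUL · l),  K_COUL = 332.0636 kcal mol⁻¹ Å e⁻²,  l = 1.14 Å

turns each slope into an equivalent atomic charge (q_pos on the O atom under
positive field, q_neg under negative field). A cheap method's energies are
then corrected frame by frame,

E_corrected = E_low − E_EAC(low, F) + E_EAC(high, F),

and scored against the high-level energies by squared Pearson correlation
and mean unsigned error. The unsigned ratio |k1|/|k2| tracks the B1/B2
population ratio obtained by classifying Fe···C≡O angles at the 90°
boundary.

## Worked example

A synthetic study with the default generator — per-method EAC dipole models,
half-normal fields of scale 0.02 e/Å², Gaussian energy noise of
0.1 kcal/mol, and a 3.45:1 two-mode angle mixture:

```r
library(eacfield)
truth <- generator_truth()     # HF / B3LYP / MP2 charge models
study <- generate_field_energy_table(truth, 10000, seed = 42)

e_mp2 <- subset(study$energies, method == "MP2")
fit <- eac_fit(study$frames$field,
               interaction_energy(e_mp2$E_total, e_mp2$E_self),
               method_label = "MP2", boot = 1000, seed = 42)
print(fit)
#> EAC fit [MP2]: n = 10000 frames
#> Sign-segmented linear fit (energy ~ field)
#>   F > 0: slope   -96.2335  intercept   0.0004  r2 0.9929  n 5001
#>   F < 0: slope    31.8921  intercept   0.0000  r2 0.9378  n 4999
#>   unsigned slope ratio |k1|/|k2| = 3.0175
#>   derived charges: q_pos = +0.2542 e, q_neg = -0.0842 e (l = 1.140 A)
#>   k1/k2 95% bootstrap CI: [2.9947, 3.0425]
```

The fitted slopes recover the generating charges (0.2541/−0.0843 e) to the
third decimal. Correcting the HF energies with the two EAC models and
scoring them against MP2:

```r
e_hf  <- subset(study$energies, method == "HF")
ei_hf <- interaction_energy(e_hf$E_total, e_hf$E_self)
fit_hf <- eac_fit(study$frames$field, ei_hf, method_label = "HF", boot = 0)
corrected <- correct_energies(ei_hf, study$frames$field,
                              fit_hf$model, fit$model)
agreement_stats(corrected, interaction_energy(e_mp2$E_total, e_mp2$E_self))
#> agreement: R^2 = 0.9810, MUE = 0.1128 kcal/mol (n = 10000)

state_ratio(generate_angle_series(truth, 10000, seed = 42))
#> B1: 7694  B2: 2306  B1/B2 = 3.337
```

The residual MUE of ~0.11 kcal/mol is the noise floor (two independent
σ = 0.1 noise streams leave a mean absolute difference of σ√2·√(2/π)), and
the recovered B1/B2 count ratio sits within binomial error of the 3.45:1
mixture weight.

`run_pipeline(pipeline_config(n_frames = 10000, seed = 1))` chains every
stage (fields → decomposition → per-method EAC fits → correction → B-state
counts) and writes a report bundle of CSV/JSON artifacts, each stamped with
the seed and a configuration hash; `inst/scripts/eacfield-pipeline.R` wraps
it for shell use. Real data enter through `read_pqr()` /
`read_pdb_geometry()` plus the CSV readers.

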