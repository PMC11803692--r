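# elastoquant

Quantitative MRI / MR elastography (MRE) analysis for preclinical brain
imaging, built around fully synthetic, ground-truth-bearing data. The
package targets the common situation in small-animal neuro-oncology
studies — longitudinal multiparametric MRI of orthotopic glioma models —
where the analysis chain (elastogram reconstruction, T2 relaxometry,
diffusion-tensor mapping, region statistics, histology quantification)
must be validated without access to raw scanner data. Every estimator in
the package can therefore be driven by a matching generator whose ground
truth is recorded, so each stage is verifiable by parameter recovery.

## What it computes

**MR elastography.** External vibration at 900 Hz induces shear waves
whose displacement is encoded into the MR phase across 4 sampled wave
phases and 3 encoding directions on a 64 × 64 × 9 voxel grid (0.3 mm
isotropic). The reconstruction chain is

1. per-slice 2-D phase unwrapping (quality-guided region growing),
2. inter-slice 2π alignment,
3. temporal first-harmonic extraction,
   `H = (2/4) Σₙ sₙ exp(−i 2πn/4)`,
4. curl decomposition `q = ∇×U` (annihilates the compressional
   component),
5. local Helmholtz inversion: under local homogeneity each curl
   component obeys `G*∇²q_c = −ρω²q_c`, and the complex shear modulus is
   estimated per voxel by least squares over the three components,
   `G* = −ρω² Σ_c q_c ∇²q_c* / Σ_c |∇²q_c|²`.

The elastogram reports the storage modulus `Gd = Re G*`, loss modulus
`Gl = Im G*`, the magnitude `|G*| = √(Gd² + Gl²)` ("stiffness", kPa) and
the phase angle `Y = (2/π)·atan2(Gl, Gd)` (0 = purely elastic, 1 =
purely viscous).

**T2 relaxometry.** Voxelwise mono-exponential fits of 30-echo trains
(TE = 7…210 ms) with a noise-floor filter: echo samples at or below four
standard deviations of the data set's noise level are discarded before
fitting (log-linear least squares, inverse-variance weights, magnitude
bias correction).

**Diffusion.** Log-linear tensor fits of 30-direction DWI at
b = 1500 s/mm², reduced to ADC (mean diffusivity) and fractional
anisotropy FA.

**Longitudinal statistics.** Region means (tumor core, corpus callosum,
needle tract, contralateral control) are assembled into a tidy
subject × week × region × metric table; paired t-tests compare time
points within a group and unpaired t-tests (pooled variance by default)
compare groups on absolute values or per-subject deltas, reported as
mean ± SEM with P ≤ 0.05 as the significance level.

**Histology.** Stained-area fraction by sample-guided RGB thresholding
(20 sampled stain pixels → per-channel mean ± 2 SD in-range rule,
conjunctive across channels) and nucleus density per 100 µm² (intensity
threshold + connected components + area filter).

**Synthetic cohort.** `default_study_design()` encodes a three-arm
longitudinal study (treatment-control n = 10, radiotherapy n = 13, sham
n = 9, imaging every 4 weeks) whose group-mean trajectories are the
published values of the emulated study; `build_longitudinal_cohort()`
draws per-subject trajectories around them, and `run_pipeline()` turns
each subject-week into simulated acquisitions, reconstructs all maps,
and reproduces the statistical report — deterministically for a given
seed.

## Worked example

```r
library(elastoquant)

## homogeneous viscoelastic brain phantom on the acquisition grid
ph  <- build_property_phantom(regions = list(brain = list(gd = 5000, gl = 2000)))
fld <- plane_wave_field(ph)                  # analytic 900 Hz shear wave
acq <- encode_wave_phases(fld, wrap = TRUE)  # wrapped 4-phase acquisition
el  <- reconstruct_elastogram(acq)
el
#> Elastogram: 64 x 64 x 9 voxels; 16730 valid
#>   median |G*| 5460 Pa, median Y 0.239; 0 voxels clipped
```

The generating modulus is `G* = 5000 + 2000i` Pa, i.e. `|G*|` = 5385 Pa
and `Y` = 0.242: the wrapped-phase chain recovers both within ~1.5% /
0.003 at the study's 8.3 voxels per wavelength.

```r
cohort <- build_longitudinal_cohort(seed = 1)
paired_timepoint_test(cohort$truth, "treatment_control",
                      "corpus_callosum", "gstar_kpa", 4, 8)
#> paired_timepoints: week8 vs week4
#>   week8                 5.449 +/- 0.3615 (SEM), n = 10
#>   week4                 3.527 +/- 0.3165 (SEM), n = 10
#>   t = 6.639, df = 9, p = 9.491e-05  (significant at alpha = 0.05)
```

This is the callosal-stiffening comparison on one simulated cohort: the
week-4 → week-8 increase around the designed group means (4.44 → 5.31
kPa) is detected by the paired test.

A command-line front end over the same functions is installed at
`inst/cli/elastoquant.R` (subcommands `simulate`, `reconstruct`,
`fit-t2`, `fit-dti`, `roi-stats`, `histo`, `run-all`).

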