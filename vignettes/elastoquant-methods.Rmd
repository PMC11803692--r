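---
title: "Models and methods behind elastoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind elastoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

elastoquant is a simulation-validated analysis chain for preclinical
multiparametric brain MRI: MR elastography (MRE) reconstruction, T2
relaxometry, diffusion-tensor reduction, longitudinal region statistics
and histology quantification. This vignette explains the models each
stage assumes, the parameters that matter, what the synthetic generators
emulate (and deliberately do not), and the numerical and design choices
a maintainer would want to know.

## The viscoelastic wave model

Tissue is modelled as a linear viscoelastic solid with complex shear
modulus `G* = Gd + i·Gl` (storage and loss modulus, Pa). A time-harmonic
displacement `u(t) = Re{U e^{iωt}}` at vibration frequency f = 900 Hz
obeys, per component and under local homogeneity,

    G* ∇²U + ρ ω² U = 0,      ω = 2πf,

with tissue density fixed at ρ = 1000 kg/m³ (the standard soft-tissue
assumption; configurable). The shear wavenumber is `k = ω√(ρ/G*)` on
the branch with `Im(k) ≤ 0`, so that `e^{-ik(r·n)}` decays along the
propagation direction in a lossy medium. At 5 kPa this gives a 2.48 mm
wavelength — 8.3 voxels at the acquisition's 0.3 mm spacing, which is
the resolution regime all recovery tests are run in.

Two forward simulators generate test fields:

* `plane_wave_field()` — the closed-form decaying plane wave, used as
  the analytic oracle.
* `solve_heterogeneous_helmholtz()` — a flux-conservative second-order
  finite-difference solve of `∇·(G*∇u) + ρω²u = 0` per displacement
  component, with the displacement prescribed on one face. The complex
  sparse system is solved directly by a banded LAPACK factorization
  (`zgbsv`) after a slice-fastest reordering that bounds the matrix
  bandwidth by (slices × rows); a 32 × 32 × 9 subject grid solves in
  about a second. The residual of the assembled system is checked
  (< 1e-8 relative) on every solve.

The scalar per-component treatment ignores mode conversion at
interfaces. That is intentional: it generates fields obeying exactly
the physics the inversion assumes, so inversion errors measure the
reconstruction, not a modelling mismatch.

**Boundary handling.** Non-prescribed faces carry either absorbing
layers (default; a quadratic ramp of added loss modulus over 6 voxels,
backed by zero displacement) or Neumann symmetry conditions. Absorbing
layers at a desk-scale aperture of one or two wavelengths are
diffraction-dominated, so the solver-vs-oracle validation instead
anchors both faces along the propagation axis with analytic Dirichlet
values and uses symmetry sides at ~35 voxels per wavelength; this
isolates the discretization error, which stays below 2%. The pipeline's
per-subject simulations drive the thin slice direction (2.7 mm path)
with Neumann sides: the resulting standing waves still satisfy the
Helmholtz equation and invert correctly, and wave nodes are dropped by
the inversion's validity filter.

## Elastogram reconstruction

The acquisition model: the MR phase is `scale·Re{U_d e^{iθ_n}}` for
encoding direction d and wave phase `θ_n = 2πn/4`, n = 0…3, plus
Gaussian phase noise, wrapped to (−π, π]. The default encoding scale
puts the peak phase at 2.5 rad so wrapping genuinely occurs. The chain:

1. **Unwrapping** — each 2-D slice independently, by quality-guided
   region growing (compiled): growth starts at the pixel with the
   smallest local wrapped-gradient energy and always expands the most
   reliable frontier pixel, so errors cannot propagate out of noisy
   regions. Output differs from input by voxelwise multiples of 2π.
2. **Slice alignment** — per-slice global 2π offsets are removed by
   bringing the median inter-slice difference into (−π, π]; a median
   jump of exactly π is resolved toward the smaller offset with a
   warning.
3. **First harmonic** — `H = (2/4) Σ_n s_n e^{-iθ_n}`; exact on a pure
   first harmonic (`A cos(θ_n + φ) → A e^{iφ}`) and exactly rejects DC.
4. **Curl** — `q = ∇×U` by central differences with the physical
   (anisotropic) spacing; the compressional (curl-free) component is
   annihilated up to discretization error. Validity erodes one voxel.
5. **Inversion** — 7-point Laplacian of each curl component, then the
   combined least-squares estimate
   `G* = −ρω² Σ_c q_c ∇²q_c* / Σ_c |∇²q_c|²` (equal weights;
   per-component median available as an option). Validity erodes one
   more voxel and additionally drops voxels whose summed Laplacian
   magnitude is below 5% of the median — voxels with no wave curvature
   to invert, e.g. standing-wave nodes.

`Gd` and `Gl` are clipped at zero for map reporting (with the unclipped
values kept in `gd_raw`/`gl_raw` and a clip flag), so the phase angle
`Y = (2/π)·atan2(Gl, Gd)` stays in [0, 1]; atan2 makes the `Gd = 0`
limit exact. The chain is invariant to the encoding scale because the
inversion is a ratio of derivatives of the same field.

**Numerical behaviour worth knowing.** With second-order stencils the
discrete Laplacian under-curves a plane wave by the factor
`sin²(kh/2)/(kh/2)²` per axis. Because the same factor enters numerator
and denominator of the ratio estimator, the inversion bias is only
~1.5% at 8.3 voxels per wavelength for oblique incidence (it would be
~5% for axis-aligned propagation, where one axis carries the whole
wavenumber — the recovery tests use oblique waves for this reason, which
also exercises all three curl components). A standalone comparison of
the discrete curl against the analytic curl, however, inherits the full
first-difference factor `sin(kh)/kh` (9.4% at 8.3 vox/λ); the 2%
agreement is therefore asserted at 20 vox/λ.

**Smoothing.** No smoothing of q is applied by default — noiseless
recovery is then limited only by discretization. Under phase noise the
Laplacian amplifies noise and the denominator `Σ|∇²q_c|²` inflates,
biasing `|G*|` low (roughly −45% at 0.05 rad noise on the subject
grids). A 3-D Gaussian pre-smoothing of the curl components
(`smooth_sigma`, in voxels) suppresses this; the scaling cancels in the
ratio for a plane wave, so moderate smoothing restores accuracy. The
pipeline default is σ = 0.8 voxel, calibrated on phantoms: at 0.05 rad
noise it recovers the homogeneous truth to within ~1%, while σ ≥ 1.2
over-smooths and biases `|G*|` up and `Y` down.

## T2 relaxometry

Mono-exponential decay `S(TE) = s0·e^{-TE/T2}` with two-channel
magnitude noise (modulus of signal-plus-Gaussian and Gaussian, the
standard magnitude-MRI model without coil-combination detail). The
noise level σ is estimated from signal-free background as
`SD/√(2 − π/2)` (the Rayleigh SD correction).

The noise filter discards echo samples at or below
`4σ` before fitting. The published description of this filter is
ambiguous — "removal of all voxels exceeding four SDs of noise level"
could drop samples or whole voxels, and "exceeding" read literally would
remove all tissue — so the noise-floor sample-exclusion reading is the
default and the voxel-mode alternative is a config switch
(`mode = "voxel"`).

The fit is log-linear least squares of `ln S` on TE with two standard
magnitude-data refinements, both exact no-ops on noiseless data:
squared-magnitude correction (`S² ← S² − 2σ²`, unbiased in the squared
domain since `E[M²] = S² + 2σ²`) and inverse-variance weights `w = S²`
(since `Var[ln S] ≈ σ²/S²`). Measured at SNR 50 (σ = 20, s0 = 1000,
T2 = 40 ms, 30 echoes): bias +2.1% with the 4σ filter versus +9.4%
without it; the flat-weight, uncorrected variant is +7.8% filtered. A
voxel needs ≥ 3 surviving echoes and a positive decay rate to be valid.

## Diffusion tensor

`ln(S_g/S_0) = −b·gᵀDg` solved by unweighted linear least squares for
the six unique tensor components (≥ 6 non-collinear directions plus one
b = 0 volume required; the design's condition number is reported). ADC
is defined as mean diffusivity (trace/3) — the standard DTI reduction,
matching the emulated study's reported magnitudes (~600–730 × 10⁻⁶
mm²/s) — and FA from closed-form eigenvalues of the symmetric 3 × 3
tensor (trigonometric method, vectorized; negative eigenvalues are
clamped to zero for FA with a flag). Noiseless synthesis round-trips to
1e-8; FA is rotation- and scale-invariant to 1e-10. The default
30-direction scheme is a fixed antipodal electrostatic-repulsion set.

## Longitudinal cohort generator

`default_study_design()` fixes the study conditions: arms
treatment-control (n = 10), radiotherapy (n = 13, a 5-animal subset
imaged at week 16), sham (n = 9); imaging at weeks 4/8/12(/16); and the
group-mean trajectories for tumor-core volume, T2, ADC, FA, |G*| and Y,
plus callosal, needle-tract and contralateral values, set to the
published group means of the emulated study. Where a week has no
printed value, the nearest printed value is carried forward; the
tumor-core week-4 ADC (600) and the sham baselines are set to plausible
healthy-tissue values, with only the printed week-4→8 callosal delta
(−1.1 kPa) constrained in the sham arm.

Per-subject truth is `group mean + b_s + e_sw` with
`Var(b) = ρσ²`, `Var(e) = (1−ρ)σ²`, so repeated values of a subject
correlate ρ across weeks. Between-subject SDs σ are not published —
only SEMs are — so the defaults are `SEM·√n` from printed values
(e.g. |G*|: 0.22·√23 ≈ 1.06 kPa). The within-subject correlation is
unknowable from group summaries; it is exposed as a parameter with
default ρ = 0.5. At these defaults the paired week-4→8 callosal
stiffening (Δ = 0.87 kPa) has a paired effect size d ≈ 0.82, i.e.
~95% power at n = 23 — consistent with the emulated study reporting it
as significant.

Subject phantoms place an ellipsoidal tumor core (calibrated to the
subject's true volume by an order-statistics rule on voxel entry
scales: the radii scale is set between the k-th and (k+1)-th smallest
normalized voxel radius so the voxelized volume matches within one
voxel), a curved callosal band, and cylindrical tract/control regions.
Moduli derive from `|G*|` and `Y` (`Gd = |G*|cos(Yπ/2)`,
`Gl = |G*|sin(Yπ/2)`), diffusion tensors are prolate with MD = ADC and
the FA-matching eigenvalue split. The band and cylinders are drawn a
few voxels thick: the local-homogeneity inversion cannot resolve
structures much thinner than a wavelength, and the pipeline's elastogram
ROI means additionally use rim-eroded masks (in-plane same-label
neighbourhoods), as manual ROIs drawn inside a structure would be.

**What the generator does not emulate:** anatomically realistic mouse
anatomy, mass effect and tissue deformation over time, contrast
enhancement or hemorrhage, coil sensitivity and B0/B1 artifacts, motion,
or registration error (maps are perfectly co-registered by
construction). Passing recovery tests therefore demonstrates
correctness of the estimators under the stated models — not robustness
to every artifact of real acquisitions.

## Statistics

Paired two-sided t-tests between time points (only subjects present at
both weeks), unpaired two-sided t-tests between groups on absolute
values or per-subject deltas. The published analysis says only
"unpaired t-tests"; the pooled-variance (Student) form is the default
and Welch an option. Results carry mean ± SEM per arm
(`SEM = SD/√n`), t, df and p; α = 0.05. No multiple-testing correction
is applied by default, mirroring the exploratory design, but a
Benjamini–Hochberg helper (`adjust_comparisons()`) is provided.
Degenerate zero-variance comparisons with equal means return p = 1 with
a warning rather than NaN.

## Histology quantification

The stained-area readout follows the sample-guided rule: 20 sampled
stain-conforming pixels give per-channel bounds mean ± 2 SD (sample SD,
n−1 — the n/(n−1) distinction is negligible at n = 20 but pinned for
exactness tests), clipped to [0, 255]; a pixel is stained iff all three
channels are in range (conjunctive rule; whether the original pipeline
was conjunctive or hue-based is not documented, so conjunctive is the
pinned default). Nuclei are segmented by intensity threshold +
connected components (EBImage) with an area filter; density is
count·100/area.

The generator draws stained pixels from a single-dye colour model: one
bounded stain-concentration factor (truncated Gaussian, unit variance,
support ±1.91 SD) drives all three channels, Beer–Lambert-like; 8-bit
quantization adds residual channel jitter. Two properties of this model
matter. First, a stain class really is a compact colour cluster —
"pixels conforming to a hue" is only a well-posed instruction for a
bounded class, and unbounded independent Gaussian channels would make
the ±2 SD conjunctive rule miss 12–14% of the class by construction.
Second, with 20-sample thresholds the dominant error is threshold
sampling noise, not class overlap; the recovery tests therefore average
the readout over 10 replicate threshold samplings, as a reader
re-sampling conforming pixels would. Measured recovery error of the
planted fraction is then ≤ 1.1 percentage points up to 20% stained.
Nucleus placement is Poisson-count random sequential adsorption of
disjoint disks (radius 0.3 µm, 0.2 µm rim gap at 0.1 µm/pixel);
placement refuses infeasible packings, and counts are recovered exactly
in the disjoint regime.

## Pipeline and reproducibility

`run_pipeline()` chains cohort → per-subject synthesis (wave solve,
echo trains, DWI) → reconstruction/fits → ROI table → comparisons →
report, writing every stage (NIfTI volumes, tidy CSVs, a text report)
plus the effective configuration next to its outputs. All randomness
derives from one root seed through named substreams
(`substream_seed()`), so a stage reproduces even when other stages'
settings change; repeated runs are byte-identical. Generators save and
restore the caller's RNG state.

Problem sizes used in the shipped tests: full 64 × 64 × 9 grids for the
reconstruction-recovery and identity checks; 32 × 32 × 9 subject grids
(reduced field of view at the acquisition's 0.3 mm resolution, keeping
8.3 voxels per wavelength) and 2–3 subjects per arm for end-to-end
pipeline checks; 200 simulated cohorts for power and 2000 replicates
for null calibration; 300 × 300 px histology images. These sizes were
chosen so the full suite runs in about a minute while every statistical
assertion retains comfortable Monte-Carlo margins.

## Known limitations

* The inversion assumes local homogeneity; estimates within ~2 voxels
  of a property interface are biased and thin structures (≲ half a
  wavelength) are not resolved — matching the physics of the emulated
  acquisition rather than a fixable defect.
* The heterogeneous solver is scalar per component (no mode
  conversion), adequate for validating the inversion but not a full
  elastodynamic model.
* The phase-to-displacement scale of the emulated hardware is unknown;
  elastograms are scale-invariant by construction, so this affects
  nothing downstream, but displacement amplitudes are nominal.
* The paired/unpaired test battery assumes approximate normality of
  region means; no mixed-effects modelling of the full longitudinal
  structure is attempted.
* Histology quantification is validated on the synthetic single-dye
  model; real slides with mixed stains, illumination gradients or
  out-of-focus regions need stain deconvolution and flat-field steps
  that are out of scope here.
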