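---
title: "Regional fetal brain T2* relaxometry: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional fetal brain T2* relaxometry: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalt2star)
```

## The problem

Quantitative T2* mapping of the fetal brain gives an indirect window on
tissue composition and oxygenation in utero: deoxyhemoglobin shortens T2*,
and at low field (0.55 T) intrinsic T2* values are long enough that even
short-T2* structures such as the deep gray matter can be quantified. The
obstacles are fetal motion — the fetus moves freely between and within
whole-volume repeats ("dynamics") of the multi-echo gradient-echo EPI
acquisition — and the coarse native resolution (3 mm isotropic) of that
acquisition.

`fetalt2star` implements the full quantitative pathway as a reusable,
testable pipeline:

1. a gestational-age (GA) parameterised digital phantom with per-slice
   rigid motion and Rician noise (`phantom_spec()`, `simulate_scan()`),
2. a simplified multichannel rigid slice-to-volume super-resolution
   reconstruction shared across the three echoes (`super_resolve()`),
3. voxelwise mono-exponential T2* mapping (`compute_t2star_map()`),
4. seven-region quantification (`regional_mean_t2star()`,
   `regional_volume()`),
5. cohort inclusion bookkeeping (`apply_inclusion_filters()`), and
6. normative GA modelling: polynomial growth curves and 2-week-bin
   percentile tables (`fit_growth_curve()`, `make_percentile_table()`).

## Signal model and relaxometry

A gradient-echo voxel decays mono-exponentially,

$$ S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2^*}, $$

sampled at TE = 42, 107, 172 ms. The default estimator is ordinary least
squares of $\log S$ on TE (`fit_loglinear()`): with three echoes it is fast,
exact on noiseless data, and its slope gives $T_2^* = -1/m$. A damped
(Levenberg–Marquardt) nonlinear fit (`fit_nonlinear()`) is provided for
noise-floor robustness; on noiseless data the two agree to machine
precision, which the test suite asserts. Log-domain fitting admits an
optional signal²-weighting (`weighting = "signal2"`) that approximates
linear-domain least squares.

Voxels with non-positive signals, non-decaying fits, or $T_2^*$ outside the
configured bounds (default 1–1000 ms, chosen to exceed the longest
ventricular fluid values in the normative table) are marked *invalid and
excluded*, never clamped: clamping would bias regional means. A
configurable minimum-first-echo-signal filter exists and is off by default,
since the reference processing chain does not document such a mask.

Because $T_2^*$ depends only on signal *ratios*, the maps are invariant to
global signal scaling; this is asserted as a property test.

## The digital phantom

The phantom is a deterministic function of `(gestational_age, grid_shape,
voxel_size, seed)`. Seven regions — eCSF shell, cortical gray-matter band,
white-matter core, deep gray matter, paired ventricles, posterior-inferior
cerebellum, inferior brainstem — are nested and offset ellipsoids whose
semi-axes scale linearly with GA so that total brain volume grows strictly
monotonically from 20 to 40 weeks. Relative region volumes were chosen to
sit near in-vivo volume fractions (ventricles a few percent of brain,
deep gray matter ~3%), because the difficulty of regional recovery is
governed by surface-to-volume ratios; the shapes themselves are schematic.
Quantification correctness depends on label bookkeeping, not anatomical
realism.

Each region receives the normative mean T2* for its GA
(`lookup_reference_t2star()`: piecewise-linear interpolation of the
2-week-bin means placed at bin midpoints 21, 23, …, 39 weeks, constant
beyond) and a fixed proton-density-like $S_0$ (fluid 1000, parenchyma
800–850, arbitrary units). Regions are homogeneous by default; a
`heterogeneity` flag adds a smooth T2* gradient along the slice axis for
sensitivity experiments, since within-region heterogeneity in vivo is not
documented for this parcellation.

### Acquisition simulation

The simulated acquisition mirrors the dynamic multi-echo EPI protocol:
3 mm in-plane pixels, 3 mm slices, three echoes per excitation, 15–30
dynamics. For every (slice, dynamic) one rigid transform is drawn —
rotations uniform within ±`motion_amplitude[1]` degrees, translations
within ±`motion_amplitude[2]` mm, about the volume centroid — and applied
identically to all three echoes: echoes of one excitation share the fetal
position, which is the premise of multichannel reconstruction. The slice
value integrates the phantom through a Gaussian slice profile (FWHM = slice
thickness, 3-point Gauss–Hermite quadrature) and a 2×2 in-plane box
average. Rician noise, $\sqrt{(v+n_1)^2+n_2^2}$ with $n_{1,2}\sim N(0,
\sigma^2)$, models magnitude images; Gaussian noise is available for
estimator comparisons. Everything is a pure function of `(inputs, seed)`.

## Reconstruction

`super_resolve()` alternates, for a configurable number of outer loops
(default 3):

* **Registration.** Each reference-echo slice is registered to the current
  volume by maximising normalised cross-correlation (NCC) between the slice
  and the slice-profile projection of the volume, with multi-start
  Nelder–Mead refinement (coarse perturbed seeds at the first iteration,
  warm starts afterwards). The reference echo defaults to the third, where
  tissue contrast is strongest. Estimated transforms are copied to the
  other echoes.
* **Outlier rejection.** A slice is excluded when its NCC falls below the
  similarity threshold (default 0.8); a dynamic is excluded when more than
  half of its slices are. Because noise attenuates NCC regardless of
  motion, scores are first corrected for attenuation by
  $\sqrt{1-\hat\sigma^2/\mathrm{var}(b)}$, with $\hat\sigma$ estimated from
  the always-background field-of-view corners (Rayleigh moment estimator).
  Noise-dominated slices get an undefined score and are kept: they carry no
  evidence of motion corruption.
* **Volume update.** A regularised least-squares inversion of the same
  slice-acquisition forward model, by conjugate gradients with first-order
  Tikhonov smoothing, warm-started from a motion-compensated scatter
  average of the *included* slices (so excluded slices have zero influence
  on the result). The Tikhonov weight defaults to the squared
  noise-to-signal ratio (floored at 2e-4 for conditioning): noiseless data
  are inverted deeply, noisy data are smoothed in proportion to their noise
  power — a discrepancy-principle choice.

With zero outer iterations the PSF-weighted initialisation is returned.
Voxels never touched by any slice are flagged invalid.

### What the registration can and cannot recover

On this smooth, near-ellipsoidal phantom, single-slice 2-D/3-D rigid
registration is genuinely ill-posed: in-plane structure varies slowly, so
combinations of tilt and translation produce near-identical slices and NCC
reaches ≥ 0.99 at parameter sets several degrees from the truth.
Through-plane translation, which changes slice content fastest, is
recovered well (tested to 0.5 mm), and the *reconstruction* remains
accurate because data consistency — not parameter identification — drives
the volume update. Textured real anatomy identifies parameters far better
than smooth ellipsoids; parameter-recovery results on this phantom are
therefore a lower bound.

### Resolution limits

The acquisition samples 3 mm pixels at 3 mm pitch; the 1.2 mm target grid
is only partially determined by a single motion-free stack orientation.
Inter-dynamic motion adds genuine in-plane diversity, so moderate motion
*improves* the conditioning of the super-resolution inverse problem.
Residual partial-volume mixing at tissue interfaces biases regional means
of small, high-contrast structures (ventricles, deep gray matter,
brainstem) by a few percent even at convergence; the same limitation is
acknowledged for the in-vivo processing chain this mirrors. The simulator
and the reconstructor share one forward model, so recovery experiments here
bound model-matched performance, not robustness to slice-profile
mis-specification.

## Regional quantification

The fine 19-label parcellation is collapsed to seven categories by an
editable YAML mapping (left/right pairs merged; corpus callosum into white
matter; vermis into the cerebellum category; third and fourth ventricles
into ventricles). The exact source-label inventory is a package convention,
documented in `inst/extdata/label_mapping.yaml`. Regional means are
computed on the voxelwise T2* map over valid in-region voxels (computing
them instead from the region-mean signal is available for sensitivity
analysis); volumes are voxel counts times the affine voxel volume.

## Normative modelling

Growth curves are ordinary least squares on the raw polynomial basis
$\{1, \mathrm{GA}, \dots, \mathrm{GA}^d\}$, default degree 2 — regional
T2* declines faster late in gestation, so a linear model underfits — with
the GA association summarised by the joint F-test of all GA terms
(per-coefficient t-tests are also reported, since either convention is
found in practice). Degree is a configuration knob recorded in outputs.

Percentile tables use 2-week half-open bins $[a, a+2)$ (the last closed at
40, matching "weeks + 6 days" bin labelling) and linear-interpolation
(type-7) quantiles; the convention is stated in the table metadata because
5th/95th percentiles of bins with 7–11 scans are sensitive to it.
`evaluate_centile()` inverts the empirical bin distribution. Repeated scans
of one subject are treated as independent data points, mirroring the
study design this reproduces; a one-scan-per-subject sensitivity path is a
matter of filtering the input table.

The synthetic control cohort (`simulate_regional_cohort()`) draws 92 scans
with per-bin counts (8, 10, 11, 9, 9, 8, 11, 8, 7, 11), GA uniform within
bins, and per-region values Gaussian around the midpoint-interpolated
normative mean with
$\mathrm{sd} = (p_{95}-p_5)/3.29$ — the normal-theory width of a 5th–95th
interval. Volumes follow a synthetic cubic-in-scale growth model anchored
at ~51 mL of cortical gray matter at 31 weeks; the published normative
table for this parcellation reports T2* percentiles only, so the volume
model is a simulation convention, not a measured reference.

## Cohort bookkeeping

`apply_inclusion_filters()` keeps scans with both sequences, GA ≥ 20
weeks, brain inside the field of view, and correctable motion, logging the
*first* failing rule per scan in the fixed order sequences → GA → FOV →
motion, so exclusion logs are deterministic. The packaged synthetic
manifest (193 scans, 145 subjects) reproduces every box of the study flow
chart: 150 scans / 114 subjects with both sequences; 8, 1 and 6 scans
excluded for GA, FOV and motion; 135 included scans from 107 subjects,
split 92 control (71 subjects) / 43 pathology (36 subjects). One published
demographic table lists 93 control outcomes where the narrative count is
92 control scans; the manifest follows the narrative and the discrepancy is
simply noted here rather than resolved.

## Problem sizes and numerical choices

The simulation studies in the test suite use a 64³ grid at 1.2 mm (end-to-
end recovery; 15 dynamics; motion up to 5°/5 mm; SNR 20 defined against
the mean tissue $S_0$) and 48³ grids for unit-level checks; cohort-level
normative runs use the regional-cohort generator rather than per-scan
reconstructions. Conjugate-gradient volume updates run 20 iterations per
outer loop (the data-term residual plateaus well before that on these
sizes); reconstruction uses 2 outer loops in the end-to-end studies.
Nelder–Mead registration uses 5 perturbed starts (±2°/±2 mm) in the first
outer iteration and single warm starts afterwards, with an early exit when
the initial NCC already exceeds 0.9995. Ties and degenerate inputs are
handled explicitly: constant slices return their initialisation with an
undefined score, empty percentile bins are emitted with n = 0, and
constant growth-curve outcomes return zero GA coefficients with an
undefined p-value.

## Known limitations

* The phantom is geometric, homogeneous within regions, and shares its
  forward model with the reconstructor; passing recovery tests bounds
  model-matched performance only.
* No EPI distortion, B0 inhomogeneity, spin-history or coil-sensitivity
  modelling; no deformable motion.
* Edge-preserving regularisation is deliberately out of scope; Tikhonov
  smoothing trades noise robustness against interface sharpness.
* The normative volume model is synthetic (see above).
* Pathology-group inference is out of scope: the cohort module stratifies
  but draws no statistical conclusions.
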