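# fetalt2star

Regional T2\* relaxometry of the fetal brain from motion-corrupted,
multi-echo low-field MRI — as a tested, reusable R pipeline.

## The problem

Between 20 and 40 weeks of gestation the fetal brain changes rapidly, and
T2\* — the effective transverse relaxation time of gradient-echo MRI — is
one of the few quantitative, functionally sensitive measurements available
in utero: deoxyhemoglobin shortens it, and at 0.55 T its values are long
enough to quantify even short-T2\* structures such as the deep gray
matter. Getting from the raw acquisition to regional normative curves
requires a chain of steps: the dynamic multi-echo gradient-echo EPI data
(TE = 42/107/172 ms, 3 mm isotropic, 15–30 whole-volume dynamics) are
corrupted by per-slice fetal motion, must be fused into 1.2 mm isotropic
volumes for all three echoes with *shared* motion estimates (multichannel
slice-to-volume reconstruction), fitted voxelwise with the
mono-exponential decay model

    S(TE) = S0 · exp(−TE / T2*),

summarised over seven merged brain regions (eCSF, gray matter, white
matter, deep gray matter, ventricles, cerebellum+vermis, brainstem), and
modelled against gestational age (GA) with polynomial growth curves and
2-week-bin percentile tables.

`fetalt2star` implements this full pathway for methodological work:
a GA-parameterised digital phantom with Rician noise and rigid per-slice
motion stands in for the scanner, and every downstream stage — rigid
slice-to-volume super-resolution, T2\* mapping, regional statistics,
cohort inclusion logic, normative modelling — is exercised against it.
It is aimed at researchers developing or validating fetal quantitative-MRI
processing.

## Worked example

Simulate a 30-week scan with moderate motion, reconstruct, fit, and
summarise:

```r
library(fetalt2star)

lookup_reference_t2star("white_matter", 27)
#> [1] 331.6        # normative white-matter mean T2* (ms) at 27 weeks

scan <- simulate_scan(phantom_spec(gestational_age = 30, grid_shape = 48,
                                   motion_amplitude = c(2, 2), seed = 1),
                      acquisition_spec(n_dynamics = 4))
rec   <- super_resolve(scan$stacks, recon_config(n_outer_iterations = 2))
map   <- compute_t2star_map(rec, mask = scan$labels$labels > 0)
stats <- regional_mean_t2star(map, scan$labels)
stats[, c("region", "mean_t2star_ms", "volume_ml", "n_valid_voxels")]
#>             region mean_t2star_ms volume_ml n_valid_voxels
#> 1             eCSF          341.4    9.5040           5474
#> 2      gray_matter          267.7   12.0372           6966
#> 3     white_matter          309.2    4.7796           2766
#> 4 deep_gray_matter          249.9    0.5426            314
#> 5       ventricles          355.5    0.4009            232
#> 6       cerebellum          292.9    0.7707            446
#> 7        brainstem          221.7    0.5944            344
```

The recovered means sit within a few percent of the ground-truth tissue
values for large regions (white matter: 309 vs 317 ms) and are biased by
partial-volume mixing for the smallest, high-contrast structures — the
expected behaviour when inverting 3 mm acquisitions onto a 1.2 mm grid,
and the reason the package reports per-region valid-voxel counts.

Normative modelling on a synthetic 92-scan control cohort drawn from the
normative table:

```r
cohort <- simulate_regional_cohort(seed = 1)
fit_region_growth(cohort, degree = 2)$brainstem
#> growth_model (degree 2, n = 92): R2 = 0.838, joint GA p = < 2.22e-16
#> (Intercept)        ga^1        ga^2
#>  288.743418   -1.129387   -0.056693

head(subset(as.data.frame(make_percentile_table(cohort)),
            region == "brainstem"), 3)
#>       region bin_start bin_end  n  mean    p5   p50   p95
#> 61 brainstem        20      22  8 241.6 225.9 242.5 255.7
#> 62 brainstem        22      24 10 231.8 215.5 232.0 247.2
#> 63 brainstem        24      26 11 223.4 211.4 222.4 237.4
```

Regional T2\* declines strongly with GA in every region, with the
brainstem near-linear and R² above 0.8 — the pattern the normative
reference table encodes.

The methods vignette (`vignettes/fetal-t2star-methods.Rmd`) documents the
models, the simulation conditions, numerical choices, and known
limitations.

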