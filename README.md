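# stripeqmri

Columnar structure–function analysis of quantitative MRI in human V2
stripes.

The secondary visual cortex (V2) of primates is tiled by repeating
pale–thin–pale–thick cytochrome-oxidase stripe cycles. Thin stripes are
color-selective, thick stripes disparity-selective, and post-mortem
histology suggests — inconsistently across staining methods — that the
stripe types are differentially myelinated. `stripeqmri` implements the
in-vivo version of this question for researchers working with
sub-millimeter 7 T data: functionally localize thin and thick stripes from
fMRI contrast z-maps, compare a myelin-sensitive quantitative parameter
(R1 = 1/T1, in s⁻¹) between stripe types with curvature deconfounding, and
assess significance with spatial-autocorrelation-preserving permutation
nulls. A first-class synthetic cohort generator makes every stage testable
without scanner data.

## The analysis in brief

For each hemisphere, with per-vertex maps over a flattened V2 patch:

1. **ROIs.** Thin = {z_color ≥ z*} \ {z_disp ≥ z*}; thick symmetric;
   vertices supra-threshold in both maps are discarded. The comparison set
   for thin stripes is V2 \ {z_disp ≥ z*} (it deliberately retains pale and
   own-stripe vertices).
2. **Deconfounding.** R1 is centered to its V2 mean, then linear curvature
   dependence is regressed out (partial-volume effects of folding are
   linear in curvature): `resid = R1 − mean_V2(R1) − β·curv`.
3. **Statistic.** `d_thin = ⟨resid⟩_thin − ⟨resid⟩_(V2∖supra-disp)`
   (area-weighted), `d_thick` symmetric; hemispheres are pooled by
   unweighted averaging.
4. **Inference.** The activation maps are replaced by variogram-matched
   surrogates (value multiset and empirical variogram γ(h) of the source
   preserved), ROIs rebuilt, and the statistic recomputed n times. With k
   null values at least as extreme as the observation, the reported p is
   inflated by three binomial standard deviations:
   `p = min(1, (k + 3σ)/n)`, `σ = √(n·p̂(1−p̂))`, `p̂ = max(k,1)/n`.

Supporting modules implement multi-echo dual flip angle FLASH relaxometry
(`S = A·sinα·(1−E1)/(1−cosα·E1)·e^(−TE·R2*)`, ESTATICS joint R2\* fit,
rational Ernst-approximation R1/PD with B1+ correction, PD(WM) = 69 pu
calibration, MTVF = 100 − PD), equi-volume cortical depth sampling,
phase-encoded retinotopy (percent signal change, high-pass at
1/(3·period), quarter-cycle discard, opposite-direction combination that
cancels the hemodynamic delay), and foveal exclusion from eccentricity
phase.

## Worked example

```r
library(stripeqmri)

# Synthetic cohort: 4 subjects x 2 hemispheres, stripe R1 offsets calibrated
# so the ideal-label contrasts are -0.005 (thin) and -0.014 s^-1 (thick)
cfg      <- cohort_config(seed = 20240901)
patch0   <- generate_patch(cfg$patch_width, cfg$patch_height, cfg$patch_spacing,
                           list(type = "zero"))
stripes0 <- generate_stripe_labels(patch0)
cfg      <- calibrate_stripe_effects(cfg, patch0, stripes0)
cohort   <- simulate_cohort(cfg)

sweep <- threshold_sweep(cohort, thresholds = c(0, 1, 1.96, 3, 4.5))
sweep[, c("threshold", "d_thin", "d_thick",
          "mean_thin_vertices", "mean_thick_vertices")]
#>   threshold   d_thin  d_thick mean_thin_vertices mean_thick_vertices
#> 1      0.00 -0.00151 -0.00415                805                 846
#> 2      1.00 -0.00368 -0.01152                904                 995
#> 3      1.96 -0.00443 -0.01384                823                 980
#> 4      3.00 -0.00455 -0.01391                820                 982
#> 5      4.50 -0.00323 -0.01418                628                 733
```

At the central threshold z = 1.96 the recovered contrasts (−0.0044 and
−0.0138 s⁻¹) sit on the calibrated ground truth; at z = 0 the ROIs are
noise-dominated and the contrasts shrink toward zero, and at very high
thresholds the thin ROI starts to starve — the reason the analysis sweeps
thresholds rather than trusting one.

Permutation inference (a few minutes; 1,000 surrogate iterations across
8 hemispheres on a reduced 24 × 12 mm patch):

```r
cfg_m    <- calibrate_stripe_effects(cohort_config(patch_width = 24, patch_height = 12,
                                            patch_spacing = 0.5, seed = 7))
cohort_m <- simulate_cohort(cfg_m)
pt <- permutation_test(cohort_m, threshold = 1.96, n = 1000, seed = 1)
pt$thin
#> <permutation_result> d_thin: observed -0.00484, k = 0 / n = 1000, p = 0.002998 (one-sided)
pt$thick
#> <permutation_result> d_thick: observed -0.01336, k = 0 / n = 1000, p = 0.002998 (one-sided)
```

Both stripe types show significantly lower R1 than the surrounding
(pale-containing) cortex — lower myelination of thin and thick stripes.
Note that with k = 0 exceedances the 3σ-corrected p-value cannot fall
below ≈ 3/n.

ROI coverage of V2 (area percent; pale is the remainder under the
tripartite assumption):

```r
h1  <- cohort$hemispheres[[1]]
roi <- define_stripe_rois(h1$color, h1$disparity, h1$patch$v2_mask, 1.96)
round(coverage_summary(roi, h1$patch$v2_mask, h1$patch$vertex_area), 1)
#>  thin thick  pale
#>    25    30    45
```

An end-to-end run (`run_full_analysis(run_config(...))`) writes the sweep
CSV, coverage table, JSON permutation summaries, the resolved YAML config
and a log, and is bit-reproducible from the config seed.

## Limitations

Synthetic patches are flat sheets with Euclidean (= geodesic) distances;
receive-bias correction of PD and off-resonance correction of B1+ maps are
out of scope (amplitudes are generated bias-free); GLM estimation of the
z-maps, segmentation, registration and V1/V2 border drawing are upstream
of this package. See the methods vignette (`vignettes/stripe-qmri-methods.Rmd`)
for the full model description and design rationale.
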