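---
title: "Methods: columnar qMRI stripe analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: columnar qMRI stripe analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stripeqmri)
```

`stripeqmri` asks whether the thin, thick and pale cytochrome-oxidase
stripe types that tile human V2 are differentially myelinated, using the
longitudinal relaxation rate R1 (s⁻¹) as a myelin surrogate and columnar
fMRI to localize the stripes. This vignette is the package's own account of
the models it implements, the parameters that matter, what the synthetic
cohort does and does not emulate, and the design choices made where the
design was genuinely open.

## 1. The stripe comparison model

Per hemisphere the inputs are per-vertex maps over a flattened V2 patch:
two session-averaged activation z-maps (color > luminance, localizing thin
stripes; depth > no-depth, localizing thick stripes), a quantitative map
(R1 or R2\*), curvature, and the V2 mask.

**ROI construction.** Thresholding the color map at z\* and removing
vertices also supra-threshold in the disparity map yields the thin ROI
(and symmetrically thick). Discarding the overlap acknowledges the BOLD
point-spread function: a vertex activated by both contrasts cannot be
assigned exclusively to one stripe type. Pale stripes cannot be localized
functionally; they are inferred indirectly, assuming a strict tripartite
division, by comparing each stripe ROI against **whole V2 minus the other
stripe type's supra-threshold set**. This comparison set intentionally
contains own-stripe and pale vertices; the calibration below accounts for
that dilution exactly.

**Deconfounding.** Cortical R1 varies with curvature (partial-volume and
myeloarchitectonic effects that are linear in curvature to first order),
and subjects differ in mean R1. Each hemisphere's map is therefore
centered to its V2 mean and linearly residualized on curvature (OLS with
intercept, fitted within V2) before any comparison. The statistic is
invariant to adding any constant and any linear function of curvature to
the map — a property the test suite verifies with injected confounds.

**Statistic and pooling.** `d_thin` is the area-weighted mean residual in
the thin ROI minus that of its comparison set; hemispheres are pooled by
unweighted averaging (each hemisphere counts equally, matching pooling
across participants and hemispheres). Area weighting is nearly uniform on
the synthetic regular grids but matters on real meshes. A vertex-pooled
variant was considered and rejected: it would weight hemispheres by ROI
size, conflating effect size with localizer quality.

**Inference.** Parametric nulls are invalid here because neighbouring
vertices are strongly dependent. The null replaces both activation maps by
surrogates that preserve each map's value multiset and empirical
variogram (Section 3), rebuilds ROIs at the same threshold and recomputes
the pooled statistic. The exceedance count k uses "at least as extreme"
(≥, the conservative reading), one-sided in the direction of the observed
statistic for the directional stripe hypothesis and two-sided for the
session-reliability analysis. Because n iterations only estimate the tail
probability, the estimate is inflated by three binomial standard
deviations, `p = min(1, (k + 3σ)/n)` with `σ² = n·p̂(1−p̂)`; at k = 0 we
substitute `p̂ = 1/n` so the correction never returns p = 0 (the reported
p is then ≈ 3/n). The whole pipeline is slightly conservative by
construction; its measured type-I error at α = 0.05 over 500 null cohorts
is well below 0.07 (test suite).

**Threshold sweep.** Because any single z\* is arbitrary, the analysis is
repeated over z ∈ {0, 0.5, …, 4.5} with per-threshold significance stars
(0.05 / 0.01 / 0.001). ROI sizes of the supra-threshold sets shrink
monotonically with z\*; note that the *exclusive* ROIs need not be
monotone at very low thresholds, where the overlap-exclusion correction
dominates — the test suite asserts monotonicity for z\* ≥ 1 only.

## 2. The synthetic cohort and its calibration

The generator (`cohort_config()`, `simulate_cohort()`) emulates the study
conditions the analysis is validated against:

| parameter | default | unit | rationale |
|---|---|---|---|
| subjects × hemispheres | 4 × 2 | — | study cohort size |
| patch | 32 × 16, 0.4 spacing | mm | flattened V2 at sub-mm sampling |
| stripe cycle / thin / thick | 8.0 / 2.0 / 2.6 | mm | macaque widths (4.0/1.0/1.3) doubled for human |
| sessions per contrast | 2 | — | maps are session averages, as acquired |
| `effect_z` | 5.0 | z per session | see below |
| activation noise | SD 1, corr. length 2 | z, mm | unit-variance z-scores; GRF noise |
| `r1_baseline` | 0.58 | s⁻¹ | mean V2 R1 |
| `delta_thin`, `delta_thick` | solved | s⁻¹ | calibrated to d = −0.005 / −0.014 |
| `noise_cv` | 11.3 | % of baseline | reported V2 R1 coefficient of variation |
| `curvature_coupling` | 0.02 | s⁻¹ per mm⁻¹ | weak linear confound the analysis must remove |
| R2\* baseline / stripe effect | 30 / 0 | s⁻¹ | null R2\* finding; configurable for power studies |

**Stripe offsets are calibrated, not free.** With area fractions
f(thin/thick/pale) and pale at baseline, the ideal-label statistic is
`d_thin = δ_thin · f_pale / (f_thin + f_pale)` (the comparison set contains
the own stripe), and symmetrically for thick. `calibrate_stripe_effects()` inverts
this, preferring the *realized* area-weighted fractions of the discrete
grid so that the noiseless true-label statistic equals −0.005 / −0.014 s⁻¹
to float precision (verified against a brute-force weighted-mean oracle).

**Why `effect_z = 5`.** The per-session in-stripe mean z is a free choice
(no stimulus-evoked effect size per stripe is available to inherit). We
require the synthetic localizer to behave like the real one across the
whole threshold sweep: ROIs must remain populated and informative up to
z\* = 4.5. Since the analyzed map averages two unit-noise sessions
(noise SD 1/√2), a per-session effect of 5 keeps in-stripe detection near
ceiling at z\* = 1.96 and non-empty ROIs at 4.5. A weaker localizer
(e.g. effect 3) lets a substantial fraction of thick-stripe vertices
escape their ROI and leak into the thin comparison set, attenuating
`d_thin` by tens of percent — a property of an underpowered localizer, not
of the method under study.

**Noise realism and its limits.** Activation noise is a Gaussian random
field (white noise spectrally filtered with a Gaussian kernel; correlation
length = lag at which autocorrelation falls to 1/e, default 2 mm). qMRI
measurement noise is white across vertices with SD 11.3 % of baseline; the
realized V2 coefficient of variation is slightly above 11.3 % because
stripe structure and the curvature coupling add variance (≈ 11.6 % under
defaults, within the reported 11.3 ± 0.7 across participants). The
generator does not emulate draining-vein geometry, B0-orientation effects
on R2\*, receive-field bias in PD, non-linear curvature couplings, or
hemodynamic variability beyond a fixed delay — so passing tests show the
*analysis* is unbiased and calibrated under its stated assumptions, not
that those assumptions exhaust real 7 T data. Seeds split hierarchically
(cohort → subject → hemisphere → map); adding subjects never changes
existing ones.

## 3. Variogram-matched surrogates

The permutation null needs maps that are random yet share the source
map's spatial autocorrelation; plain shuffles destroy it and make every
test anti-conservative. A surrogate draw: (1) permute the source values;
(2) smooth with an exponential-decay kernel over the k = 30 nearest
neighbours at each candidate scale {0.5, 1, 2, 4, 8} mm; (3) regress the
source's empirical variogram on the smoothed map's
(`γ_src ≈ β·γ_sm + c`, unweighted over 25 equal-width bins truncated at
the 25th distance percentile — long-range bins are noisy and irrelevant);
(4) form `√max(β,0)·(smoothed − mean) + √max(c,0)·white noise`,
re-centred; (5) re-impose the source's exact value multiset by rank
matching (so thresholded null ROIs see realistic z distributions); and
keep, across scales, the finished candidate whose own variogram has the
lowest SSE against the source. Selecting on the finished candidate rather
than the intermediate regression fit matters: rank matching and the noise
term perturb the variogram, and judging scales before those steps leaves
a heavy tail of poorly matched draws (beat-rate against naive shuffles
~90 %, versus ~99 % with finished-candidate selection, at twice the draw
cost). The trade-off: for a truly uncorrelated source the selection makes
surrogates match *slightly* better than plain shuffles (a few percent of
the sill at short range) instead of being exactly indistinguishable from
them; the suite verifies no spurious autocorrelation beyond that residual
is injected.

## 4. Relaxometry

The forward model is the spoiled gradient-echo steady state with
mono-exponential R2\* decay. Estimation mirrors the standard
multi-parameter-mapping chain: a joint log-linear OLS per location with
one shared R2\* slope and per-contrast TE = 0 intercepts (uniform weights
— the weighted variant is out of scope), followed by the rational
small-angle/short-TR dual flip angle estimator for R1 and the amplitude,
with flip angles multiplied by the measured B1+ efficiency beforehand. The
exact two-point Ernst inversion (bisection) exists in the test suite as an
independent oracle, never as the production path. The rational estimator's
accuracy at the default protocol (TR 25 ms, FA 5°/24°) is documented by
the suite's error grid: it *under*estimates R1 with error shrinking
monotonically from 2.2 % at R1 = 0.3 s⁻¹ to below 2 % from 0.4 s⁻¹ upward
(1.7 % at the V2 value 0.58 s⁻¹). PD is calibrated so its white-matter
mean is 69 pu (scale-invariant); MTVF = 100 − PD. Locations with
non-positive signals or non-physical signal ordering are flagged invalid
and counted, never raised — aborting a whole-map fit for single bad voxels
is not an option.

## 5. Depth sampling and geometry

The equi-volume depth fraction assumes the local column's cross-section
varies linearly between the white (A_w) and pial (A_p) boundary areas;
the fraction enclosing volume fraction ν has the closed form
`x = (−A_w + √((1−ν)A_w² + ν·A_p²))/(A_p − A_w)`, reducing to the
equi-distant x = ν when the areas agree (relative tolerance 1e−9). Local
areas are barycentric one-ring areas on each boundary surface; the
level-set formulation of the same model is out of scope at desk scale.
Volume conservation is verified against numerical integration to 1e−10.
Curvature is the cotangent-Laplacian discrete mean curvature, signed by
the vertex normal (sphere with outward orientation → +1/R); boundary
vertices of open meshes have incomplete one-rings and report 0. Volume
sampling follows the NIfTI RAS convention with 0-based voxel indices;
nearest-neighbour ties round half-down toward the lower index, and
vertices outside the volume are flagged invalid.

## 6. Retinotopy

Phase-encoded series are converted to percent signal change, high-pass
filtered at 1/(3·period) Hz, and the first quarter stimulus cycle is
discarded. The high-pass is a zero-phase DFT-domain filter (bins strictly
below the cutoff, DC included, are zeroed): at the study's cutoff a
windowed-sinc kernel with a usable stop band would need more taps than the
run has samples, whereas the DFT filter has exactly unit gain at the
stimulus frequency. Discarding initial samples shifts the time origin, so
the retained series carries a `t_offset` attribute and phases are
re-referenced to the stimulus clock — without this the opposite-direction
combination silently fails at small delays. The reverse-direction
coefficient is conjugated before complex averaging with the forward one;
the common hemodynamic phase lag then cancels exactly (delays up to a
quarter period), which the suite verifies to 1e−6 rad on exact-bin
series; end-to-end recovery through the filter is accurate to ~1e−3 rad
(spectral leakage of the non-integer cycle count). The foveal exclusion
mask drops vertices whose eccentricity phase lies within the inner third
of the full cycle around the foveal origin (configurable fraction and
origin).

## 7. Problem sizes and numerical choices

The test suite and acceptance script choose desk-scale sizes: full-size
patches (32 × 16 mm, 0.4 mm spacing, 3321 vertices) wherever only
statistics are computed (effect recovery uses 20 replicate cohorts of
4 × 2 hemispheres); reduced patches (16 × 8 mm, 0.8 mm, 231 vertices) for
permutation-heavy studies (type-I error: 500 null cohorts × 200
iterations; reliability calibration: 200 repetitions × 100 surrogates).
Surrogate samplers are precomputed per geometry and shared across
cohorts. All randomness flows from explicit seeds through a multiplicative
hash (`cohort → subject → hemisphere → map`), and identical configs
reproduce outputs bit-for-bit.

## 8. Known limitations

Pale stripes are inferred, never measured; the tripartite assumption is
inherited from the biology. R1 is a myelin surrogate, not a myelin
measurement. The flat-patch geometry ignores geodesic distortions of real
flattening. The binomial 3σ correction floors attainable p-values at
≈ 3/n, so small permutation counts cannot produce very small p-values by
construction. PD maps are generated and fitted bias-free; real
receive-field bias removal is upstream of this package.
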