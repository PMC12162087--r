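---
title: "Localizing putative human FST in simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing putative human FST in simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fstloc)
```

`fstloc` re-creates, on fully synthetic data, the analysis chain used to
functionally localize the putative human homolog of macaque area FST (pFST)
and to distinguish it from the neighboring hMT/MST motion complex. This
vignette explains the forward models, the parameters that matter, and the
design decisions taken where the procedure is genuinely underdetermined —
the level of detail a reader needs to judge what a passing test suite does
and does not establish.

## 1. The localization logic

Three localizer experiments are simulated per hemisphere:

* **2D motion** — dots alternating between moving (radial in/out, clockwise,
  counterclockwise) and static in 15 s blocks; the contrast mean(moving) −
  static isolates classic motion selectivity and peaks in hMT/MST.
* **Changing-disparity stereomotion (3D motion)** — two disparity-defined
  surfaces moving in antiphase through depth (±18 arcmin, reversing every
  second) versus a temporally scrambled control that preserves the same
  static disparity content. The coherent − scrambled contrast isolates
  motion-in-depth selectivity and is the operational signature of pFST.
* **Motion opponency** — 300 dots at 5 deg/s, either paired (opposite
  directions within 0.5 deg, crossing once per 0.1 s lifetime) or unpaired.
  The unpaired − paired contrast measures opponency suppression, strong in
  hMT/MST and weak in FST.

Delineation then thresholds both motion contrast maps at the 95th
percentile of the hemisphere, takes the largest 4-connected cluster of the
2D map as hMT/MST, and searches the 3D-not-hMT/MST remainder for a
contiguous cluster adjacent to hMT/MST whose centroid lies anterior and/or
inferior to it (score Δcol + Δrow > 0; ties to the larger cluster). If no
candidate qualifies, both thresholds are lowered in 1-percentile steps to
the 90th. Validation compares opponency, R1 = 1/T1 (a myelin proxy) and pRF
properties between the two ROIs.

## 2. The synthetic hemisphere

The cortical "surface" is a flat 96 × 96 vertex grid with 4-connectivity;
columns run posterior→anterior and rows dorsal→ventral, so "anterior and/or
inferior" is simply "greater column and/or greater row". Three regions are
laid down as the nearest-n vertices to configured centers, assigned in the
order hMT/MST (296 vertices), pFST (95, which therefore forms a crescent
hugging hMT/MST's anterior/inferior flank), then a V1-like control patch
(200). The 296/95 sizes echo the degrees of freedom of the study-style
tests (one-sample df 295/94; pooled two-sample df 296 + 95 − 2 = 389).

The grid is larger than the regions by design: the percentile thresholds of
the delineation procedure keep the top 5–10 % of the hemisphere, and on a
real surface (~150 000 vertices) an ROI of a few hundred vertices sits far
inside that mask. A sheet on which the regions occupied more than 5 % of
the vertices would make a 95th-percentile mask structurally smaller than
the region — the threshold, not the data, would then bound the achievable
overlap. Region fraction below 5 % is therefore part of emulating the real
measurement geometry.

Per-region tuning means (all configurable):

| parameter | background | V1-like | hMT/MST | pFST | meaning |
|---|---|---|---|---|---|
| gain2d (PSC) | 0 | 1.2 | 2.0 | 0.8 | moving − static response |
| gain3d (PSC) | 0 | 0.2 | 1.0 | 1.5 | coherent-stereomotion response |
| coh_sel | 0 | 0.1 | 0.5 | 1.0 | fraction of gain3d lost in the scrambled control |
| opponency | 0 | 0.05 | 0.6 | 0.15 | fractional suppression by paired dots |
| prf_gain (PSC) | 0 | 2.5 | 2.0 | 1.5 | stimulus-vs-blank mapping amplitude |
| prf_sigma (deg) | 3 | 1 | 4 | 20 | pRF size |
| T1 (s) | 1.331 | 1.28 | 1.19 | 1.26 | R1 = 1/T1 brackets 0.75–0.84 s⁻¹ |

`coh_sel` = 0.5 for hMT/MST encodes that the area is somewhat, but not
fully, selective for coherent 3D motion; no quantitative value exists for
it, so it is a modeling choice. `prf_gain` is deliberately distinct from
`gain2d`: mapping stimuli drive a stimulus-vs-blank response (2–3 % signal
change is typical), whereas `gain2d` is a moving-minus-static difference.

Vertex-level spread is multiplicative with CV 0.15 and spatially smooth
(Gaussian correlation length 2 vertices, via smoothed random fields). Both
choices emulate surface maps: cortical tuning varies smoothly, and iid
vertex noise would fragment percentile masks into specks in a way real
surface data does not. The printed within-ROI t values of the study imply
much larger vertex CVs (~0.5), but those are real-data quantities that
also absorb measurement noise and are not reproduction targets here.

A second, "atlas" label set is the truth displaced by a seeded offset of up
to ±2 vertices plus one random dilation or erosion — a stand-in for
anatomical-atlas misalignment, so DICE-against-atlas exercises the same
code path the study uses against a parcellation atlas.

## 3. BOLD forward model

Per-TR neural amplitudes are boxcars: moving blocks drive `gain2d`, coherent
blocks `gain3d`, scrambled blocks `gain3d·(1 − coh_sel)`, unpaired blocks
`gain2d`, paired blocks `gain2d·(1 − opponency)`; static and blank drive
nothing. The hRF is a double gamma (response gamma shape 7, rate 1 — mode
exactly 6 s; undershoot shape 16 weighted 1/6; 32 s support; unit sum, so
convolution preserves block amplitude). Simulated raw signal is
`baseline + conv(neural) + drift + noise` with baseline 100, a linear drift
of 1 PSC per run, and iid Gaussian noise of SD 0.5 PSC by default; analysis
then converts to percent signal change (100·(y − mean)/mean), exactly as
the surface-based analysis it emulates does. The finite baseline makes PSC conversion a
~1 % multiplicative bias on recovered amplitudes — visible in the 2 %
tolerance of the noiseless recovery tests, and representative of the real
measurement. Temporally autocorrelated noise is not modeled (the GLM
applies no prewhitening either, matching the described analysis).

GLM betas use the Moore–Penrose pseudoinverse of the design (one
hRF-convolved boxcar per condition + constant + drift [+ six nuisance
regressors when provided]); repeated runs are fit separately and averaged
with equal weights. The four moving-direction betas are averaged (not
summed) before subtracting static — the choice affects only the scale of
the 2D contrast.

## 4. pRF estimation

The pRF model is a plain 2D circular Gaussian (no compressive exponent),
normalized by its untruncated integral so that a full-field stimulus yields
a response of at most 1 and σ is separable from the fitted scale.
Predictions are mask·Gaussian sums over the aperture raster (101 × 101 over
±12.2° by default; tests use 61 × 61), hRF-convolved; a scale and an
additive constant are fitted per candidate by least squares, so a
candidate's R² is the squared correlation between prediction and data.

Fitting is coarse-to-fine: an exhaustive grid over (x0, y0) at 1° spacing
and 20 log-spaced σ levels in [0.25, 24]°, scored in one matrix product
against precomputed predictions (ties resolved to the first candidate in
row-major (x0, y0, σ) order), then Nelder–Mead refinement of
(x0, y0, log σ) from the grid optimum. Refinement is confined to the
searched domain (|x0|, |y0| ≤ radius; σ within the grid's range): outside
the aperture the likelihood is nearly flat in σ, and an unconstrained
simplex drifts to arbitrarily large sizes on noisy data. The returned fit
never scores below the grid optimum, and an all-constant series is flagged
degenerate with R² = 0.

Two identifiability limits matter when interpreting recovery tests. First,
a Gaussian much smaller than the bar width (3.05° at the default 8-step
protocol) that sits mid-strip predicts identically for every small σ —
below ~1° size is not identifiable from the bar protocol, so zero-noise
recovery is asserted for σ in [1, 5]°. Second, pRFs at or beyond the
aperture radius respond with only a small fraction of their mass (the
full-field response of a σ = 20° Gaussian inside a 12.2° field is ~0.17),
so their amplitude — and hence their explained variance — is intrinsically
low. This is the mechanism the bias simulation quantifies.

The null model ("stimulus-contrast" / ON–OFF) predicts from the stimulated
area per timepoint, hRF-convolved. Model comparison uses the combined
bar + wedge + ring protocol, since the study fitted pRFs on all mapping
runs.

## 5. The bias simulation

For every cell of sizes {1, 5, 10, 15, 20}° × eccentricities
{0, 3, 6, 9, 12}° × noise SDs {0, 0.5, 2} PSC, 50 voxels (15 in the
analysis script; cell means are unchanged in expectation) are placed at
uniformly random polar angles, their responses to the sweeping bar
simulated, and (x0, y0, σ) re-estimated; bootstrap SEs (100 resamples)
summarize each cell. Noise levels are not stated in the source procedure;
{0, 0.5, 2} spans noiseless to noise-dominated. The simulated amplitude is
the raw Gaussian-overlap response (≤ 1 PSC) rather than a peak-normalized
one: amplitude loss for large pRFs is precisely what produces their low
explained variance, and equalizing SNR across sizes would remove the
phenomenon under study (a `normalize = "peak"` option retains the
alternative).

At zero noise, recovery is exact for every size — the generative and
fitting models coincide. With noise, aperture-sized pRFs collapse to
severely underestimated sizes and centrally biased eccentricities, and the
size bias grows with noise up to a saturation plateau once the signal is
fully buried (between SD 0.5 and 2 for σ ≥ 15°, the bias is statistically
flat). Tests therefore assert strict zero-versus-nonzero growth plus
tolerance-bounded monotonicity across the noise grid, and compare
eccentricity bias between small (1°) and aperture-sized (15, 20°) pRFs
rather than demanding strict monotonicity over all five sizes, where
sub-degree inversions within Monte-Carlo error occur.

## 6. Delineation details and degenerate inputs

Percentiles use linear interpolation (R's type-7 quantile); a constant map
passes everywhere, which is the documented degenerate behavior. The
threshold walk covers [95, 90] in steps of 1. pFST candidates must be
4-connected clusters of at least 5 vertices within a distance of 3 vertices
of hMT/MST: percentile masks always cover 5–10 % of the sheet, so isolated
supra-threshold noise vertices always exist, and the manual procedure this
code emulates draws contiguous activation peaks, not single vertices. When
two candidates qualify, the larger anterior/inferior score wins (ties to
the larger cluster); if none qualifies at the 90th percentile, pFST is
returned empty and flagged rather than guessed. An optional `search_mask`
reproduces the anatomical restriction to the lateral-occipital/inferior-
temporal window.

DICE is 2|A∩B|/(|A|+|B|) with the empty–empty case defined as 0; centroid
distances are Euclidean between unweighted vertex centroids; surface area
is vertex count × per-vertex area (1 mm² default).

## 7. Statistics

One-sample (df n−1), pooled two-sample (df n₁+n₂−2; Welch behind a flag)
and paired (df pairs−1) t tests follow the study's df conventions; p values
are two-sided except the per-hemisphere one-tailed two-sample tests of the
group report, which test in the direction of the group-level difference. No
multiple-testing correction is applied, matching the described analysis.
Vertices are treated as independent samples within a hemisphere — the
printed dfs imply the same treatment — although vertex values are spatially
correlated by construction; the group-level inference rests on hemispheres,
not vertices. A lightweight cohort simulator (hemisphere-level random
effect + vertex spread) drives the group-report calibration tests: under a
null cohort with equal ROI means the paired test rejects at the nominal
rate, and under the designed effects all four measures separate in the
expected directions.

## 8. What the synthetic data do and do not show

The generator reproduces the design of the experiments (block timing, dot
kinematics, disparity trajectories, aperture geometry), the qualitative
tuning structure of the three regions, smooth vertex heterogeneity, drift
and thermal noise, and atlas misalignment. It does not model cortical
folding or mesh topology, vascular or motion artifacts, temporally
correlated noise, session-to-session registration error, or any real
between-subject variability beyond seeded resampling. Passing tests
therefore establish that the *procedure* — stimuli through statistics — is
implemented faithfully and behaves as the study reports under conditions
the study describes; they are not evidence about real cortex, and the
study's real-data effect sizes (specific t values, median R², overlap
percentages) are deliberately not reproduction targets.

## 9. Problem sizes used by the tests

The test suite runs the full 96 × 96 hemisphere pipeline (clean recovery
plus 20 noisy seeds), pRF fitting on a 61-cell raster with 96–288
timepoints, a reduced bias grid (4 sizes × 2 eccentricities × 3 noise
levels × 10 voxels × 10 seeds), and 200 null cohorts for the type-I check —
sizes chosen so the whole suite completes in a few minutes while every
assertion retains comfortable Monte-Carlo margins.
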