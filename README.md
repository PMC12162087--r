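# fstloc — simulation-based functional localization of putative human FST

The fundus of the superior temporal sulcus (FST) is a motion-processing area
well characterized in macaques — driven by complex 3D motion, only weakly
suppressed by opponent motion, less myelinated than MT — but its human
homolog ("pFST") has no established localizer. A localization strategy that
works on the cortical surface is: contrast a **2D-motion localizer** (moving
vs static dots, which drives hMT/MST) with a **changing-disparity
stereomotion localizer** (coherent motion-in-depth vs temporally scrambled
disparity, which drives pFST), threshold both contrast maps at the 95th→90th
percentile, and label the 3D-active-but-not-2D-active cluster adjacent and
anterior/inferior to hMT/MST as pFST. Motion opponency (unpaired − paired
dots), the R1 = 1/T1 myelin proxy, and population receptive field (pRF)
properties then validate the distinction.

`fstloc` implements that entire analysis chain as a tested, fully synthetic
pipeline for R:

* **Stimuli** — block schedules and frame-accurate dot kinematics for the
  2D-motion localizer (250 limited-lifetime dots, 10° aperture, speed
  `12·√(ecc/10)` deg/s for radial and `12·(ecc/10)^{1/8}` for rotational
  motion), the ±18 arcmin antiphase disparity trajectories with per-second
  scrambling, the paired/unpaired opponent dot field (300 dots, 5 deg/s,
  0.1 s pair lifetime), and bar/wedge/ring pRF-mapping apertures (12.2°
  radius).
* **Synthetic hemisphere** — a flat cortical sheet with ground-truth V1-like,
  hMT/MST-like (296 vertices) and pFST-like (95 vertices) regions carrying
  per-vertex 2D/3D gains, opponency indices, pRF parameters and T1.
* **GLM** — double-gamma hRF, boxcar designs with drift and nuisance
  regressors, percent signal change, pseudoinverse betas, run averaging, and
  the three localizer contrasts.
* **pRF fitting** — coarse-to-fine estimation of the 2D circular Gaussian
  `(x0, y0, σ)` (exhaustive grid, then Nelder–Mead) against a
  stimulus-contrast (ON/OFF) null model whose prediction tracks stimulated
  area only.
* **ROI delineation** — percentile thresholding, 4-connected clustering,
  scenario classification, the anterior/inferior position criterion, and the
  DICE / centroid-distance / surface-area overlap metrics.
* **Bias simulation** — recovery of pRF size and eccentricity across true
  sizes 1–20°, centers 0–12°, and noise levels, with bootstrap SEs, showing
  why pRFs at or beyond the stimulus aperture are systematically
  underestimated.
* **Group statistics** — one-sample / pooled two-sample / paired t tests with
  the study's df conventions, decile profiles, and a cohort-level report.

## Worked example

The numbered scripts under `analysis/` run the study end to end
(`Rscript analysis/01_simulate.R`, … `05_bias_simulation.R`), writing tables
under `results/`. Delineating one synthetic hemisphere at the default
conditions (noise SD 0.5 PSC):

```r
library(fstloc)
loc <- localize_hemisphere(config = default_config(seed = 1))
loc$metrics
#>     roi n_vertices dice_truth dice_atlas centroid_dist_truth area_mm2 threshold            scenario
#>  hMTMST        297      0.998      0.839              0.0349      297        95 overlap_3d_superset
#>    pFST         94      0.995      0.864              0.0603       94        95 overlap_3d_superset
```

Both regions are recovered almost exactly (DICE ≈ 1 against the ground
truth; lower DICE against the deliberately jittered "atlas" labels), in the
majority activation scenario where the 2D localizer activates a subset of
the 3D activation. The validation statistics on the same hemisphere show
the expected direction of every effect, e.g. stronger opponency suppression
in hMT/MST than pFST (`t(389) = 32.1`) and higher R1 (`t(389) = 16.0`).

Fitting the pRF and stimulus-contrast models to sampled vertices
(`analysis/04_prf_model_comparison.R`) reproduces the diagnostic signature
for receptive fields that exceed the mapping aperture:

```
 region r2_prf r2_contrast sigma_hat true_sigma r2_gap
 hMTMST 0.1743     0.03765     4.021       4.30 0.1367
   pFST 0.0218     0.00182     0.254      20.47 0.0199
 V1like 0.5338     0.04829     0.912       1.03 0.4855
```

V1-like vertices are fit far better by the pRF model than by the ON/OFF
model; pFST-like vertices (true σ ≈ 20° versus a 12.2° aperture) explain
almost no variance under either model and their fitted sizes collapse below
1° — pRF mapping cannot delineate such a region, which is why the
localizer contrast is needed.

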