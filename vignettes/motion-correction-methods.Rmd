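---
title: "Partial-angle motion correction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-angle motion correction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(parmoco)
```

This vignette is the package's own account of the science it implements:
the reconstruction and motion model, the parameters that matter, what the
synthetic data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The correction pipeline

A cardiac CT scan acquires fan-beam projections continuously while the
heart beats; any reconstruction window of tube-angle width `π + 2Γ`
(fan angle `Γ`) spans roughly 200 ms at 0.25 s/rotation, long enough for
coronary arteries to move several millimetres. The pipeline implemented
here corrects for that motion without segmenting anything:

1. **Gating** (`select_gating_window`): the contiguous view range of
   width `π + 2Γ` centred on the view whose time maps to the target R-R
   phase.
2. **Rebinning** (`rebin`): fan rays `(β, γ)` are resampled to parallel
   coordinates `θ = β + γ`, `s = R sin γ` (equiangular detector), with
   bilinear interpolation. The parallel grid is restricted to the fully
   covered angular range `[β_min + Γ/2, β_max − Γ/2]`, so no invalid
   corner samples exist; its span is then exactly `π + Γ`.
3. **Conjugate PARs** (`reconstruct_par`): ramp-filtered backprojection
   of the first and the last `Γ` of parallel angles. The two partial
   images see the same set of ray orientations (their centres differ by
   exactly `π`) but are acquired half a rotation apart, so any
   difference between them is motion, not angular-sampling differences.
4. **Edge extraction** (`bandpass`): an isotropic radial band-pass with
   pass band `[0.1, 0.3]·π` rad/sample. Limited-angle backprojection
   concentrates its shading artifacts at low frequencies; the band-pass
   keeps the edge information that registration needs.
5. **Motion estimation** (`register_ffd` / `estimate_motion`): cubic
   B-spline free-form deformation between the band-passed PARs,
   minimising SSD plus a light bending-energy penalty, coarse-to-fine.
6. **Linear motion model and compensated backprojection**
   (`temporal_scale`, `mc_backproject`): displacement at view time `t`
   is `α(t)·d(x)`, `α = (t − t_target)/(t_end − t_start)`, zero at the
   target (midpoint) time; each target-frame pixel collects its filtered
   ray value at the displaced radial position.

The uncorrected baseline (`fbp_reconstruct`) is the same short-scan
weighted FBP without step 5-6.

## 2. Parameters

| parameter | default | units | role |
|---|---|---|---|
| fan / PAR angle `Γ` | 52 | deg | scanner aperture; PAR span fixed to it |
| rotation time | 0.25 | s | half-rotation = 125 ms PAR separation |
| gating width | `π + 2Γ` | rad | minimum for two conjugate PARs |
| band-pass | [0.1, 0.3] | π rad/sample | edge extraction on PARs |
| transition softness | 0.1 | fraction of cutoff | raised-cosine mask edges |
| control spacing | 3.6 (finest) | mm | FFD resolution; levels 14.4/7.2/3.6 |
| levels | 3 | — | dyadic control-grid refinement |
| `lambda` | 1e-3 | — | bending energy vs (scale-normalised) SSD |
| `sigma_factor` | 0.1 | of spacing | Gaussian pre-smoothing per level |
| displacement cap | 14.3 | mm | assumed max displacement per 125 ms |
| `mu_water` | 0.02 | mm^-1 | HU conversion reference |

The PAR angle trades completeness of edge information against the
temporal resolution of the PAR images themselves; it is fixed to the fan
angle here. The displacement cap reflects the assumed maximum coronary
excursion between the two PAR time points; the registration box-bounds
control coefficients by it and globally rescales the final field if the
evaluated displacement still exceeds it (a global rescaling preserves
smoothness, unlike per-pixel clipping).

`lambda` and `sigma_factor` were fixed by a grid search on the
synthetic-warp recovery fixture (a band-passed PAR image warped by a
known smooth B-spline field): `lambda` in the 1e-4…1e-2 range trades
recovery sharpness against noise robustness, with 1e-3 a good middle;
for `sigma_factor`, heavier smoothing than ~0.1 of the control spacing
was found to *merge the oscillatory ridges* of band-passed PAR images
and create false correspondence basins (an inward wall motion can then
lock onto an outward match), so the pyramid smoothing is deliberately
light. The SSD is normalised by the fixed image's maximum, making
`lambda` image-scale-free. Optimization is L-BFGS-B with the analytic
gradient, initialised at the zero field, deterministic throughout; line
searches occasionally terminate abnormally near the optimum because the
image gradient is itself sampled — the best iterate is kept and the
per-level objective trace is stored in the field's diagnostics.

## 3. The synthetic data generator

`preset_phantom()` builds ECG-driven analytic phantoms; all projections
are exact line integrals through time-frozen ellipses (the object moves
*between* views, as in a real scan), so there is no inverse crime: the
reconstruction grid never enters the simulation.

* `xcat_like` — beating-heart analog: body ellipse (0 HU, large enough
  that its boundary stays outside the 250 mm reconstruction FOV, as for
  a real thorax), contracting myocardial annulus (100 HU), two blood
  pools of distinct contrast (350/180 HU, left vs right heart analog),
  three 3 mm, 450 HU artery disks riding mid-wall at the RCA/LAD/LCX
  positions. Kinematics: smoothstep interpolation between a diastolic
  and a systolic configuration with rapid contraction over roughly R-R
  5–38 %, a short end-systolic pause, fast early-diastolic relaxation
  ending near 53 %, and a long diastasis plateau — so R-R 30 % is a
  fast-moving phase and R-R 70 % a quiescent one, mirroring clinical
  phase selection. Mid-wall excursion between the two configurations is
  ≈ 5 mm (inter-PAR displacements of 2–4 mm at 60–100 bpm, peak
  velocities of order 30–60 mm/s — mid-range for coronary motion). A
  1.0/0.7 mm whole-heart harmonic sway is superimposed because a real
  heart is never perfectly still, even in diastasis.
* `mocomo_like` — six artery rods (3/4/5 mm, 350–450 HU, one of each
  size with an interior low-density stenosis inclusion) on a 50 mm ring
  in a water cylinder, under rigid orbital rotation (±0.16 rad ≈ 8 mm)
  plus a 2 mm translation.
* `alpha_like` — pulsating balloon (radius 30 ± 4 mm, contrast
  configurable in the 250–300 HU range) with two artery rods attached to
  its surface.
* `static` — the `xcat_like` layout with all amplitudes zero.

Overlap semantics are painting order (later primitives cover earlier
ones); presets are strictly nested, which lets `snapshot()` convert
painting into an additive decomposition with exact analytic line
integrals, and non-nested partial overlap is rejected. Projections are
noiseless by default so that algorithmic performance is measured in
isolation; `add_noise()` provides seeded Poisson counting noise for
realism studies.

**What the generator does not emulate:** anatomical surface detail,
3D vessel tortuosity and through-plane motion (the package is a 2D
axial implementation; multi-slice axial imaging is repeated 2D),
respiratory drift, contrast-bolus dynamics, beam hardening, scatter and
detector physics. Passing tests therefore demonstrate correctness of
the algorithmic chain and its behaviour under controlled motion, not
clinical performance.

## 4. Numerical choices

* Coordinates: x to the patient's right, y up, tube angle from +y,
  radians internally; pixel centres at `(i + 0.5 − n/2)·px` (0-based).
* Rebinning uses the full measurable radial range `|s| ≤ R sin(Γ/2)`,
  which makes the covered parallel span exactly `π + Γ` and the PAR
  centres exactly `π` apart; row times are taken from the central-ray
  fan view (the ±γ spread of source times feeding one parallel row,
  ≤ 18 ms, is ignored — the linear model needs one time per row).
* Ram-Lak kernel with exact discrete values and `Δs` scaling (optional
  Hann apodization, off by default to match noiseless simulation);
  zero-padded FFT convolution.
* Short-scan weights: cos² taper over the `span − π` overlap in the
  parallel domain; conjugate weights sum to 1 by construction.
* PAR images use uniform weight inside their span: they are feature
  images for registration, not quantitative reconstructions.
* The registration direction is fixed = first PAR; the estimated field
  maps first-PAR positions to last-PAR positions, and the compensation
  evaluates it at target-frame pixels (the `O(|d|²∇d)` error of not
  inverting the half-field is accepted under the displacement cap).
* Contributions whose displaced radial position leaves the measured
  range are dropped and counted (`dropped` attribute).
* Degenerate inputs: a zero field reproduces `backproject()`
  bit-identically (same code path); an empty primitive list rasterizes
  to zeros; zero-variance paired differences give t = 0, p = 0.5 with a
  degenerate flag.
* SSIM uses the 11×11 Gaussian window (σ 1.5), K1 = 0.01, K2 = 0.03,
  with the dynamic range taken from the reference ROI (HU images are
  not 8-bit; the choice is configurable). Profile stability uses the
  population SD of the pooled samples.

## 5. Problem sizes used by the test bench

The packaged experiments run at the sizes the package was designed
around: full geometry (736 channels, 720 views/rotation) with a 256²,
250 mm reconstruction grid for the beating-heart suite, the static null
check and the profile-stability experiment; a reduced geometry (368
channels, 360 views/rotation) with a 128² grid for the single-purpose
oracles (known-motion compensation, synthetic-warp recovery, disk
accuracy), where pixel-relative tolerances are the quantity of
interest. The supersampled (4×4) rasterized phantom at the target time
serves as ground truth throughout.

## 6. Known limitations

* 2D axial only; no cone-beam, helical or multi-slice geometry.
* The linear-in-time motion model is exact only for uniform linear
  motion; the known-motion oracle isolates exactly that case, and the
  smoothstep kinematics of the beating preset deliberately bend it.
* Conjugate PARs share one angular aperture, so the motion component
  along edges invisible to that aperture is under-determined; the
  B-spline regularity fills it in. Recovery is therefore better for
  motion across the aperture's edge normals — visible in the per-case
  spread of the evaluation suite.
* Very large inter-PAR displacements (approaching the 14.3 mm cap)
  can push the band-passed ridge patterns past the SSD capture range;
  the generator's default kinematics stay within the regime the
  registration can follow, as a real scanner protocol would by
  selecting quiescent phases.
* No iterative refinement (alternating motion/image updates) and no
  per-structure motion models, by design: the method's selling point is
  being segmentation-free and single-pass.
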