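# parmoco

Cardiac motion correction for fan-beam CT from less than one gantry
rotation of data, with a fully synthetic test bench.

Motion artifacts — blurred or doubled coronary arteries, shading and HU
bias over the myocardial wall — remain a central problem of cardiac CT.
`parmoco` implements a segmentation-free motion-correction pipeline built
around conjugate **partial-angle reconstructions** (PARs), together with
everything needed to exercise it end to end without any scanner data: an
ECG-driven dynamic analytic phantom, a time-resolved fan-beam projector,
and the evaluation metrics used to score the result. It is aimed at
people developing or teaching tomographic motion-correction methods.

## The method

For a target cardiac phase, a gating window of tube-angle width
`π + 2·Γ` (fan angle `Γ = 52°`) is selected, centred on the target. After
fan-to-parallel rebinning, two PAR images are reconstructed from the
first and last `Γ` of parallel view angles. These are *conjugate* —
their central view directions differ by `π`, so they see the same ray
set — but are acquired half a rotation (125 ms at 0.25 s/rotation)
apart. A radial band-pass (pass band `[0.1, 0.3]·π` rad/sample) extracts
edge information while discarding the shading artifacts of limited-angle
backprojection. A multi-resolution cubic B-spline free-form-deformation
registration (control spacing 14.4 → 7.2 → 3.6 mm, SSD + light bending
energy, displacements capped at 14.3 mm) estimates the motion field
`d(x)` between the two PAR time points. Assuming locally linear motion
in time, the displacement of view time `t` relative to the target
(midpoint) time is `α(t)·d(x)` with `α = (t − t_target)/(t_end −
t_start)`, and a motion-compensated weighted filtered backprojection
accumulates every filtered parallel ray at the displaced position
`x + α·d(x)`. Short-scan redundancy is handled with a smooth cos² taper
in the rebinned parallel domain.

## Worked example

```r
library(parmoco)

phantom <- preset_phantom("xcat_like", heart_rate = 80)  # beating heart
geo     <- system_geometry()                             # 52 deg fan, 0.25 s/rot
scan    <- forward_project(phantom, geo, scan_timeline(geo, 4))
grid    <- recon_grid(256, 250 / 256)                    # 250 mm FOV

rec <- sculli_reconstruct(scan, target_phase = 0.3, grid)
print(rec)
#> <sculli_recon> phase 0.30 (target time 0.2250 s)
#>   window: views 365..933, 284.0 deg of tube angle
#>   motion field: 97 x 97 controls @ 3.6 mm, max |d| 6.11 mm
#>   dropped contributions: 0

truth <- rasterize(snapshot(phantom, rec$window$target_time), grid,
                   supersample = 4)
rois <- artery_rois(phantom, rec$window$target_time)
evaluate_images(truth, rec$fbp, rec$image, rois)
#>   case roi mssim_fbp  mssim_mc rmse_fbp   rmse_mc
#> 1      RCA 0.6639383 0.8807888 36.56764 22.581974
#> 2      LAD 0.7981322 0.9097993 22.33762 17.307267
#> 3      LCX 0.8047475 0.9679934 22.33645  9.591491
```

The per-ROI mean structural similarity (MSSIM, 1 = identical to the
motionless ground truth) rises and the ROI RMSE (in HU) falls for every
coronary-artery analog; `rec$fbp` holds the uncorrected short-scan FBP
image from the same gating window for comparison. A command-line front
end (`inst/cli/parmoco`) wraps the same functions as `simulate`,
`recon`, `estimate-motion`, `evaluate`, `make-fixtures` and `demo`
subcommands, reading a YAML configuration and writing HDF5/NIfTI/CSV.

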