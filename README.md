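# cine5d

Respiratory-resolved 3D cardiac cine MRI ("5D" imaging: x-y-z-cardiac-
respiratory) in R, end to end: a digital cardiorespiratory phantom and
multi-coil k-space simulator, CIRCUS Cartesian undersampling, per-heartbeat
sorting with view sharing, absolute 3D respiratory motion tracking by
deformable registration, k-means respiratory binning, compressed-sensing
(k-t SPARSE-SENSE) reconstruction, and left/right-ventricular volumetry
with the paired statistics that compare end-expiration (EE) with
end-inspiration (EI).

It is aimed at MR-physics and image-analysis researchers who want a fully
controlled, ground-truthed sandbox for free-breathing cardiac cine methods:
every stage of the pipeline can be run, perturbed and validated against the
phantom's analytic truth without any scanner data.

## The method in brief

A continuous, ECG-recorded bSSFP-style acquisition samples the (ky, kz)
plane with CIRCUS: concentric square rings around DC, one point per ring
per interleave at fractional arc `u(r,t) = frac(t*phi + c*r/R_max)` (golden
ratio `phi ~ 0.618`, spiral parameter `c = 1.5`), with 75% partial Fourier
on all three axes. Readout lines are sorted into heartbeats by the ECG
triggers; each beat is reconstructed at ~4 mm resolution from the central
k-space band with nearest-neighbour view sharing, and registered to a
reference beat by a multi-resolution symmetric-demons scheme. The mean
deformation over the central quarter-FOV box is the beat's absolute 3D
displacement (mm). k-means (k = 4, 10 restarts, lowest inertia) bins the
beats into respiratory phases; the cluster with the most positive
superior-inferior (x) centroid is EE, the most negative is EI, and the
respiratory depth is the EE-EI centroid distance

    dd = sqrt((c1x-c2x)^2 + (c1y-c2y)^2 + (c1z-c2z)^2).

Per respiratory phase, lines are assigned to cardiac phases (10 views per
segment, i.e. 40 ms at TR 4 ms) and the cine is reconstructed by solving

    argmin_x  1/2 ||E x - y||^2 + lambda_t * TV_cardiac(x)

with SENSE encoding E and cyclic temporal total variation, by proximal
gradient descent with an exact per-voxel TV proximal map. Ventricles are
segmented by Hough-circle initialisation plus an elliptically refined
Chan-Vese level set (manual covering seed for the RV), and
`EF = (EDV - ESV)/EDV * 100` is computed per respiratory phase.

## Worked example

```r
library(cine5d)

cfg     <- phantom_config(n_coils = 4)       # 64x64x24 over 256x256x120 mm
phantom <- make_phantom(cfg)
sched   <- circus_schedule(cfg$matrix_size[2:3])   # c = 1.5, pf = 0.75
bundle  <- simulate_acquisition(phantom, sched, duration_s = 60)

beats <- sort_beats(bundle)
low   <- lowres_beat_volumes(bundle, beats)        # ~4 mm beat volumes
trace <- track_motion(low$volumes, low$spacing)    # absolute 3D displacement
bins  <- kmeans4(trace, restarts = 10, seed = 2)
resp_metrics(bins, trace, hr_bpm = beats$hr_bpm,
             beat_t_ms = (beats$trigger_ms + beats$next_trigger_ms) / 2)
```

```
<resp_metrics>
  resp rate 14.3 brpm, depth (Dd) 6.22 mm, EE:EI ratio 1.53
  portions (%): EE=33.3, EI=21.8, mid-inspiration=17.2, mid-expiration=27.6
  HR (bpm): EE=54.9, EI=64.9, mid-inspiration=60.0, mid-expiration=57.6
```

The trace dwells at end-expiration (EE holds a third of the heartbeats,
half more than EI), and respiratory sinus arrhythmia shows as a ~10 bpm
slower heart rate at EE than at EI. `run_end_to_end()` continues the chain
— coil-map estimation, EE/EI cine reconstruction, LV/RV segmentation — and
compares the recovered ejection fractions and respiratory metrics against
the phantom's analytic ground truth; on the default phantom the EE-phase LV
EF lands within one point of the true 61.5%.

Benchmark harnesses: `benchmark_tracking_scale()` measures tracking RMSE at 4 mm
resolution for small (±2 mm) and large (±8 mm) motion; `benchmark_asynchrony()`
compares 3D against 1D self-gated respiratory binning when the chest wall
lags the heart (thoracoabdominal asynchrony). A thin CLI wrapper lives at
`inst/cli/cine5d` (`simulate | bench-a | bench-b | e2e`).

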