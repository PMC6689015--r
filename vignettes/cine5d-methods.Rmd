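---
title: "Respiratory-resolved 3D cardiac cine: models, parameters and validation design"
author: "cine5d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-resolved 3D cardiac cine: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cine5d` implements a complete free-breathing "5D" cardiac MRI chain —
x-y-z resolved over both the cardiac and the respiratory cycle — and a
digital cardiorespiratory phantom that makes every stage testable without
scanner data. The pipeline is:

1. **Continuous Cartesian acquisition** with CIRCUS undersampling and ECG
   recording (`circus_schedule()`, `simulate_acquisition()`);
2. **per-heartbeat sorting** of readout lines and low-resolution beat
   volumes with nearest-neighbour view sharing (`sort_beats()`,
   `lowres_beat_volumes()`);
3. **absolute 3D respiratory motion tracking** by deformable registration
   of each beat volume to a reference beat (`track_motion()`);
4. **k-means binning** of heartbeats into four respiratory phases with
   end-expiration (EE) / end-inspiration (EI) identification (`kmeans4()`);
5. **k-t SPARSE-SENSE reconstruction** of a 3D cine per respiratory phase
   (`bin_kspace()`, `ktss_reconstruct()`);
6. **ventricular volumetry** (Hough-initialised elliptically refined level
   sets; ESV/EDV/SV/EF) and the paired statistics comparing EE with EI
   (`segment_cine()`, `chamber_volumes()`, `compare_phases()`).

# The digital phantom

The phantom is a torso ellipse containing a two-ventricle heart: the LV
cavity is an ellipsoid inside an ellipsoidal myocardial shell, and the RV
cavity is a laterally offset ellipsoid minus the LV epicardium, which gives
the crescent-shaped cross-section seen in short-axis views. Blood pool,
myocardium, chest-wall fat and remaining torso have piecewise-constant
proton-density-like intensities (1.0, 0.45, 0.8, 0.25) with a soft edge of
about one voxel; there is no relaxation or banding simulation. Contraction
interpolates the cavity semi-axes between end-diastole and end-systole with
activation `a(p) = sin^2(pi p)` of the cardiac phase `p`, so ED sits at the
R-wave and ES at mid-cycle, with dwell at both extremes. Ground-truth LV
cavity volumes are closed-form ellipsoid volumes; RV truth is voxelised on a
1 mm grid because the crescent has no closed form.

Coordinates: array axis `x` (also the readout) is the vertical axis of the
short-axis plane and the dominant (superior-inferior) respiratory axis;
positive `x` means the heart moves up. Slices are stacked along `z`.
k-space indices are 0-based with DC at `floor(N/2)`; transforms are unitary.

## Respiration, RSA and the chest wall

The heart displacement is `x(t) = -depth * sin(pi t / T)^(2n)` (plus scaled
in-plane components), with `n = resp_asymmetry`. For `n = 1` this is a pure
sinusoid; for the default `n = 2` the heart dwells near end-expiration
(displacement 0, the most positive position) and makes brief excursions to
end-inspiration — matching the observation that more heartbeats are
collected at EE than at EI. A slow seeded depth modulation
(`resp_jitter_frac`) provides cycle-to-cycle variability. A chest-wall fat
layer follows the same waveform with a configurable phase lag
(`asynchrony_phase_rad`); the bellows trace records the chest wall, not the
heart, which is what makes the thoracoabdominal-asynchrony experiments
possible. Note that only at `n = 1` is a lag of `pi` exactly anti-phase;
the asymmetric waveform has even harmonics, so its anti-phase correlation is
about -0.9.

Respiratory sinus arrhythmia modulates the instantaneous heart rate between
`heart_rate_base - rsa_amplitude` at EE and `+rsa_amplitude` at EI; R-wave
times are generated by stepping through this rate function, so RR intervals
lengthen at end-expiration.

## Default study conditions

Chosen once to emulate a healthy-adult free-breathing protocol at desk
scale, and used by tests and the acceptance script:

| parameter | default | why |
|---|---|---|
| matrix / FOV | 64 x 64 x 24 over 256 x 256 x 120 mm | 4 x 4 x 5 mm voxels; 4-5 mm slices as in the acquisition protocol |
| coils | 8 | 8-channel cardiac array |
| TR | 4 ms | protocol value |
| heart rate | 60 bpm, RSA +/- 6 bpm | typical adult resting rates; EE slower than EI |
| respiration | 14.5 brpm, 8 mm SI peak-to-peak, in-plane fraction 0.3 | typical adult rate; mid-range depth |
| LV cavity | ED (25, 25, 35) mm, ES (18, 18, 26) mm | EDV ~92 mL, EF ~61.5%, healthy-range values |
| scan length | 60-90 s | scaled down from the 2.5-min protocol to desk runtime |
| noise | 2% of peak signal per sample | SNR ~50 per coil sample |

The simulator quantises time into states — 20 cardiac-phase bins and
0.25 mm displacement quanta — and renders/FFTs each distinct state once, so
a 90 s multi-coil scan is simulated in about a minute. The quantisation
error is bounded by half a quantum (0.125 mm of displacement; 1/40 cardiac
cycle), far below the 4 mm tracking resolution and the 40 ms cardiac bins.

# CIRCUS sampling

The phase-encode plane is partitioned into concentric square rings around
DC (ring 0 is the central 2 x 2 block). One interleave takes one point per
ring; within interleave `t` the position along ring `r`'s perimeter is the
fractional arc `u(r, t) = frac(t * phi + c * r / R_max)` with `phi` the
golden-ratio conjugate and `c = 1.5` the spiral twist (`c = 0` gives a
radial-like spoke). Points falling outside the 75% partial-Fourier band, or
already used in the ring's current pass, are re-drawn at the nearest free
perimeter slot. Each ring therefore exhausts all of its in-region points
before reusing any; small central rings cycle much faster than the
periphery, which is exactly the variable-density property the
reconstruction relies on. A strict "every point at most once per full
cycle" is impossible with one-point-per-ring interleaves (inner rings hold
fewer points than the outer rings need interleaves), so per-ring no-repeat
cycles are the implemented invariant, and the tests assert it at that
granularity. Partial Fourier along the readout is asymmetric truncation
with zero-filling — linear and simple, at the cost of mild ringing.

# Motion tracking

Per-beat volumes use the central k-space band corresponding to 4 mm
resolution, filled by nearest-in-time view sharing (positions acquired in
the beat always come from the beat itself, so sharing affects mainly the
high frequencies), inverse FFT and root-sum-of-squares coil combination.
All lines of a beat are used: most data are diastolic, so beat-to-beat
differences are dominated by respiration.

Registration is a multi-resolution (3-level) demons scheme: a symmetric
intensity-difference force (average of fixed and warped-moving gradients),
Gaussian fluid smoothing of each update (sigma 1 voxel), Gaussian elastic
smoothing of the field (sigma 0.6 voxels), displacement capped per
iteration, on range-normalised magnitudes. Mutual information (32-bin joint
histogram) or SSD is the convergence monitor; a run is flagged
non-converged when the monitor keeps improving at the iteration cap or the
field has not settled. The absolute displacement of a beat is the mean
field over the central box covering 1/4 of the FOV per axis — a box, not a
segmented mask. Fields are stored in mm so resolution changes cannot
silently rescale traces.

Two properties of this estimator matter for interpretation. First,
view-shared beat volumes mix data from neighbouring beats, which slightly
compresses the apparent motion amplitude; the symmetric force keeps the
regression slope of estimated versus true SI displacement near 0.9 at the
default conditions. Second, the per-beat noise of the trace is roughly
1 mm RMS at 4 mm tracking resolution — small against breathing but not
against the 2-3 mm spacing of respiratory-phase cluster boundaries, which
caps the attainable bin-assignment Dice (below).

# Respiratory binning

`kmeans4()` runs Lloyd's k-means (via `stats::kmeans`) on the per-beat
3-vectors, 10 random restarts, keeping the lowest inertia; k is fixed at 4
phases. The cluster with the most positive x centroid is EE, the most
negative is EI; the two mid phases are named by x order only (the temporal
direction is not used, and mid-expiration/mid-inspiration naming is
therefore a convention). Respiratory depth is the Euclidean EE-EI centroid
distance; data portions are beat-count percentages; average motion is the
mean distance of a phase's points from their centroid; per-phase heart rate
averages the member beats' instantaneous rates; the respiratory rate is the
spectral peak of the SI trace (a bellows-based estimate is also reported).

Ground truth for bin-assignment accuracy is defined as the quartiles of the
true SI displacement (EE = top quartile, EI = bottom). Because the
asymmetric waveform places 30-35% of beats in the EE cluster versus the
quartile's 25%, even a perfect tracker cannot reach Dice 1 against this
reference; about 0.8 is the practical ceiling, and the package's 3D
tracking reaches it at the default conditions. The 1D self-gating surrogate
reaches about 0.7 when breathing is synchronous and collapses under
thoracoabdominal asynchrony, which is the motivation for 3D tracking.

# Reconstruction

Each respiratory phase is reconstructed independently (no regularisation
across respiration, minimising temporal smoothing across the respiratory
dimension). The model is SENSE encoding — unit-norm coil maps estimated
from the time-averaged central k-space, unitary FFT, sampling at the binned
(ky, kz, cardiac-phase) cells with duplicate acquisitions averaged — and
the objective

```
argmin_x 0.5 ||E x - y||^2 + lambda_t * TV_cardiac(x)
```

with cyclic finite differences along the cardiac axis (the cine loops).
The solver is proximal gradient descent with unit step (||E|| <= 1 by
construction); the 1D cyclic TV proximal map is evaluated per voxel by dual
projected gradient (10 inner iterations). The objective is tracked and must
be non-increasing; five consecutive increases abort with diagnostics.
`lambda_t` defaults to 2% of the largest temporal-difference magnitude of
the zero-filled reconstruction — a scale-free heuristic exposed as
`lambda_frac` — because no reference value exists for this quantity.
Iteration caps (30-60) and the 1e-5 relative-change stopping rule are
config values.

# Segmentation and function

The LV is initialised per slice by a Hough transform: gradient-magnitude
edges are cross-correlated with annulus kernels over the radius search
range; the consensus in-plane center is taken from the top-scoring slices
(spurious circles in chamber-free slices score systematically lower), and
slices far from consensus are flagged rather than segmented. A Chan-Vese
(piecewise-constant) level set then evolves from the circle with local
(windowed) region statistics, periodic soft attraction toward its best-fit
ellipse — the contour may deform beyond circularity but stays chamber-like
— plus a hard containment radius, a 3x-area leakage guard, and
seed-component selection. The RV uses the same evolution from a manual
covering circle; because a covering RV seed usually overlaps the nearby LV,
the already-segmented LV chamber (union over the cycle, dilated 6 mm
toward the wall) is excluded from the RV evolution. In the phantom studies
the "manual" RV seed is derived from the known geometry, standing in for
the operator.

Volumes are voxel counts times voxel volume over the included slices
(phases where segmentation found nothing are excluded and flagged, not
counted as empty hearts); ED/ES are the maximum/minimum phase volumes;
`EF = (EDV - ESV)/EDV x 100`; the EE-EI change is `(EI - EE)/EE x 100`
computed per pair. `compare_phases()` wraps the paired two-tailed t-test
(with the exact degenerate-difference limits: t = 0, p = 1 for identical
pairs), the Mann-Whitney test for group contrasts, and Pearson correlation,
all at alpha 0.05.

# Validation design and problem sizes

The built-in studies (also used by `scripts/acceptance.R`) are:

- **Tracking vs motion scale**: per-beat volumes rendered directly at 1 mm
  in-plane resolution, low-passed to the 4 mm tracking grid, sinusoidal SI
  motion spanning +/-2 mm and +/-8 mm; per-beat displacement RMSE must stay
  below half a tracking voxel (2 mm). This is a registration-only design —
  no k-space stage — so it isolates tracking accuracy, and 16-40 beats per
  configuration keep it fast.
- **Asynchrony**: free-breathing scans (48 x 48 x 16 over 192 x 192 x 96 mm,
  4 coils, 40-60 s) with the chest wall lagging the heart by 0 or pi/2.
  Both the 3D trace and the 1D self-gating trace are k-means binned and
  compared with quartile truth; 3D must beat 1D under asynchrony.
- **End-to-end**: the default phantom, 60-90 s scans (about 60-90 beats);
  EE and EI cines are reconstructed (the two phases the functional analysis
  compares) and the whole report is checked against the phantom's analytic
  truth: LV EF within 5 points, depth within 30% of the truth-binned
  oracle, slower HR at EE, more data at EE.

What passing these studies does **not** show: the phantom has
piecewise-constant contrast (no relaxation, banding, or flow), rigid heart
displacement (no intra-beat nonrigid respiratory deformation), perfectly
detected R-waves, and no arrhythmia, so the results bound algorithmic
correctness, not in-vivo robustness.

# Known limitations

- The CIRCUS point-selection formula is this package's concrete dialect of
  an interleaved golden-ratio construction; it satisfies the interleaving,
  variable-density and incoherence properties the reconstruction needs, and
  is isolated in one function so an alternative dialect can be swapped in.
- Demons tracking shows mild amplitude compression on strongly view-shared
  data (slope ~0.9); depth estimates inherit part of this bias.
- EI reconstructions use the smallest data share (about 20% of beats) and
  are accordingly the noisiest; their volumetry is reported but only the
  EE-phase EF carries an accuracy guarantee in the phantom studies.
- Basal-slice inclusion is a configuration choice (`slice_range`); the
  phantom studies include all slices.
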